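component,points,threshold
energy_kj,1,335
energy_kj,2,670
energy_kj,3,1005
energy_kj,4,1340
energy_kj,5,1675
energy_kj,6,2010
energy_kj,7,2345
energy_kj,8,2680
energy_kj,9,3015
energy_kj,10,3350
satfat_g,1,1
satfat_g,2,2
satfat_g,3,3
satfat_g,4,4
satfat_g,5,5
satfat_g,6,6
satfat_g,7,7
satfat_g,8,8
satfat_g,9,9
satfat_g,10,10
total_sugars_g,1,4.5
total_sugars_g,2,9
total_sugars_g,3,13.5
total_sugars_g,4,18
total_sugars_g,5,22.5
total_sugars_g,6,27
total_sugars_g,7,31
total_sugars_g,8,36
total_sugars_g,9,40
total_sugars_g,10,45
sodium_mg,1,90
sodium_mg,2,180
sodium_mg,3,270
sodium_mg,4,360
sodium_mg,5,450
sodium_mg,6,540
sodium_mg,7,630
sodium_mg,8,720
sodium_mg,9,810
sodium_mg,10,900
fvn_percent,1,40
fvn_percent,2,60
fvn_percent,5,80
fibre_nsp_g,1,0.7
fibre_nsp_g,2,1.4
fibre_nsp_g,3,2.1
fibre_nsp_g,4,2.8
fibre_nsp_g,5,3.5
fibre_aoac_g,1,0.9
fibre_aoac_g,2,1.9
fibre_aoac_g,3,2.9
fibre_aoac_g,4,3.9
fibre_aoac_g,5,4.7
protein_g,1,1.6
protein_g,2,3.2
protein_g,3,4.8
protein_g,4,6.4
protein_g,5,8
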