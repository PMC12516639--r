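#' Stratified area sampling by deprivation quintile
#'
#' Neighbourhood selection follows a two-step stratified design: areas are
#' stratified into five Index of Multiple Deprivation quintiles (quintile
#' 1 = most deprived), six areas are drawn per quintile with at most one
#' per ward, and the visit order is block-randomised so every weekly block
#' mixes quintiles. In the most deprived quintile selection is
#' deterministic: the most deprived area within each designated priority
#' ward.
#'
#' @name area-sampling
#' @keywords internal
NULL

#' Assign deprivation quintiles from ranks
#'
#' Splits areas into five groups by deprivation rank (rank 1 = most
#' deprived). When the frame size is not divisible by five, the larger
#' groups sit at the most-deprived end (ceiling-first allocation). The
#' assignment is monotone: a lower rank never lands in a higher-numbered
#' quintile than a higher rank.
#'
#' @param frame Data frame with columns `area_id` and `imd_rank` (positive,
#'   unique ranks).
#' @param n_quintiles Number of strata (default 5).
#' @return `frame` with an added `imd_quintile` column.
#' @export
#' @examples
#' assign_quintiles(data.frame(area_id = letters[1:7], imd_rank = 1:7))
assign_quintiles <- function(frame, n_quintiles = 5) {
  stopifnot(is.data.frame(frame), "imd_rank" %in% names(frame))
  r <- frame$imd_rank
  if (any(r <= 0) || anyDuplicated(r))
    stop("assign_quintiles: ranks must be positive and unique",
         call. = FALSE)
  n <- nrow(frame)
  if (n < n_quintiles)
    stop("assign_quintiles: need at least ", n_quintiles, " areas",
         call. = FALSE)
  sizes <- rep(n %/% n_quintiles, n_quintiles)
  extra <- n %% n_quintiles
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- rep(seq_len(n_quintiles), sizes)
  frame$imd_quintile <- q[rank(r)]
  frame
}

# Draw n areas from one quintile's sub-frame, at most one per ward:
# rejection sampling up to `cap` attempts, then a ward-first fallback
# (sample n distinct wards, then one area within each).
draw_one_per_ward <- function(sub, n, cap = 10000) {
  if (length(unique(sub$ward_id)) < n)
    stop("select_sample: quintile ", unique(sub$imd_quintile)[1],
         " has fewer than ", n, " distinct wards", call. = FALSE)
  for (i in seq_len(cap)) {
    pick <- sub[sample.int(nrow(sub), n), , drop = FALSE]
    if (!anyDuplicated(pick$ward_id)) return(pick$area_id)
  }
  wards <- sample(unique(sub$ward_id), n)
  vapply(wards, function(w) {
    cand <- sub$area_id[sub$ward_id == w]
    cand[sample.int(length(cand), 1)]
  }, character(1))
}

#' Select the stratified area sample
#'
#' For the most deprived quintile the selection is deterministic: within
#' each priority ward, the area with the lowest deprivation rank. For the
#' remaining quintiles, areas are drawn uniformly at random without
#' replacement subject to at most one area per ward.
#'
#' @param frame Sampling frame with `area_id`, `imd_rank`, `ward_id` and
#'   `imd_quintile` columns (see [assign_quintiles()]).
#' @param n_per_quintile Areas per quintile (default 6).
#' @param priority_wards Ward ids driving the quintile-1 selection; must
#'   number `n_per_quintile`.
#' @param seed Integer seed.
#' @return Data frame of selected areas: `area_id`, `imd_quintile`,
#'   `ward_id`, `imd_rank`.
#' @export
select_sample <- function(frame, n_per_quintile = 6, priority_wards,
                          seed = 1) {
  stopifnot(all(c("area_id", "imd_rank", "ward_id", "imd_quintile") %in%
                  names(frame)))
  if (length(priority_wards) != n_per_quintile)
    stop("select_sample: need exactly ", n_per_quintile,
         " priority wards", call. = FALSE)
  set.seed(seed)
  picks <- list()
  q1 <- frame[frame$imd_quintile == 1, , drop = FALSE]
  sel1 <- vapply(priority_wards, function(w) {
    cand <- q1[q1$ward_id == w, , drop = FALSE]
    if (!nrow(cand))
      stop("select_sample: priority ward '", w,
           "' has no quintile-1 area", call. = FALSE)
    cand$area_id[which.min(cand$imd_rank)]
  }, character(1))
  picks[[1]] <- unname(sel1)
  for (q in sort(unique(frame$imd_quintile[frame$imd_quintile > 1]))) {
    sub <- frame[frame$imd_quintile == q, , drop = FALSE]
    if (nrow(sub) < n_per_quintile)
      stop("select_sample: quintile ", q, " holds fewer than ",
           n_per_quintile, " areas", call. = FALSE)
    picks[[q]] <- draw_one_per_ward(sub, n_per_quintile)
  }
  sel <- frame[frame$area_id %in% unlist(picks),
               c("area_id", "imd_quintile", "ward_id", "imd_rank")]
  sel <- sel[order(sel$imd_quintile, sel$imd_rank), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Block-randomise the visit order
#'
#' Splits the selected areas into weekly blocks such that, when block size
#' permits, every block contains at least one area from each quintile
#' (with six areas per quintile and five blocks, each block holds one
#' quintile twice). When blocks are smaller than the number of quintiles
#' the coverage constraint is vacuous and a seeded permutation is used.
#' Within-block order is random.
#'
#' @param plan Selection data frame with `area_id` and `imd_quintile`
#'   (see [select_sample()]).
#' @param n_blocks Number of blocks; must divide the number of areas.
#' @param seed Integer seed.
#' @return Data frame `area_id`, `imd_quintile`, `week_block`,
#'   `visit_order` (overall 1..n).
#' @export
block_randomise <- function(plan, n_blocks = 5, seed = 1) {
  n <- nrow(plan)
  if (n %% n_blocks != 0)
    stop("block_randomise: ", n_blocks, " blocks do not divide ", n,
         " areas", call. = FALSE)
  set.seed(seed)
  block_size <- n %/% n_blocks
  quintiles <- sort(unique(plan$imd_quintile))
  k <- length(quintiles)
  if (block_size >= k) {
    counts <- table(factor(plan$imd_quintile, levels = quintiles))
    if (any(counts < n_blocks))
      stop("block_randomise: quintile ",
           paste(quintiles[counts < n_blocks], collapse = ", "),
           " has fewer areas than blocks; coverage infeasible",
           call. = FALSE)
    resample <- function(v) v[sample.int(length(v))]
    block_of <- integer(n)
    spare <- integer(0)
    for (q in quintiles) {
      idx <- resample(which(plan$imd_quintile == q))
      block_of[idx[seq_len(n_blocks)]] <- resample(seq_len(n_blocks))
      spare <- c(spare, idx[-seq_len(n_blocks)])
    }
    # deal remaining areas into remaining block capacity
    cap <- rep(block_size, n_blocks) - tabulate(block_of[block_of > 0],
                                                n_blocks)
    block_of[resample(spare)] <- resample(rep(seq_len(n_blocks), cap))
  } else {
    block_of <- rep(seq_len(n_blocks), each = block_size)[sample.int(n)]
  }
  ord <- order(block_of, stats::runif(n))
  out <- plan[ord, c("area_id", "imd_quintile"), drop = FALSE]
  out$week_block <- sort(block_of)
  out$visit_order <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Select the validation sub-sample
#'
#' A fraction of areas (10 % by default — three of thirty) is revisited
#' independently by a second researcher to assess data collection
#' reliability. Selection is uniform without replacement, taking the
#' ceiling of `fraction * n` areas.
#'
#' @param plan Selection data frame with `area_id`.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of selected `area_id`s.
#' @export
select_validation_subsample <- function(plan, fraction = 0.10, seed = 1) {
  if (fraction <= 0 || fraction > 1)
    stop("select_validation_subsample: fraction must be in (0, 1]",
         call. = FALSE)
  set.seed(seed)
  n <- nrow(plan)
  k <- ceiling(fraction * n)
  plan$area_id[sample.int(n, k)]
}
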