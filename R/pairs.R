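#' Generate A-B/A-C pair specifications
#'
#' Each pair couples a cue word with an outdated picture B and a replacement
#' picture C drawn from two different visual categories. The six ordered
#' (B, C) category combinations are filled as evenly as the pair count allows,
#' and exactly half of all pairs are assigned to the RetPrac condition
#' (balanced within each category combination as far as counts permit).
#'
#' @param config a \code{\link{experiment_config}}.
#' @param seed integer seed; output is deterministic given the seed.
#' @return data.frame with columns \code{pair_id}, \code{cue_id},
#'   \code{category_B}, \code{category_C}, \code{condition}.
#' @export
make_pairs <- function(config, seed = 1L) {
  n <- config$n_pairs
  cats <- config$categories
  if (n %% 2L != 0L) stop("invalid config: n_pairs must be even")
  combos <- expand.grid(category_C = cats, category_B = cats,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$category_B != combos$category_C,
                   c("category_B", "category_C")]
  combos <- combos[order(match(combos$category_B, cats),
                         match(combos$category_C, cats)), ]
  k <- nrow(combos)
  set.seed(seed)
  counts <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0L) {
    extra <- sample.int(k, rem)
    counts[extra] <- counts[extra] + 1L
  }
  rows <- rep(seq_len(k), counts)
  # condition assignment: alternate within each combo; combos with odd counts
  # alternate their starting condition so the global split is exactly half
  cond <- character(n)
  odd_start <- 0L
  for (i in seq_len(k)) {
    idx <- which(rows == i)
    if (!length(idx)) next
    start <- if (length(idx) %% 2L == 1L) {
      odd_start <- odd_start + 1L
      if (odd_start %% 2L == 1L) "RetPrac" else "Restudy"
    } else "RetPrac"
    base <- if (start == "RetPrac") c("RetPrac", "Restudy") else c("Restudy", "RetPrac")
    cond[idx] <- rep(base, length.out = length(idx))
  }
  ord <- sample.int(n)
  out <- data.frame(
    pair_id = sprintf("pair%03d", seq_len(n)),
    cue_id = sprintf("cue%03d", seq_len(n)),
    category_B = combos$category_B[rows][ord],
    category_C = combos$category_C[rows][ord],
    condition = cond[ord],
    stringsAsFactors = FALSE
  )
  stopifnot(sum(out$condition == "RetPrac") == n %/% 2L,
            all(out$category_B != out$category_C))
  out
}
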