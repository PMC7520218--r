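# Independent brute-force oracles, deliberately naive: they enumerate labelled
# individuals instead of using the closed forms under test.

# Expected richness of a subsample of n individuals: average the number of
# distinct species over every one of the C(N, n) unordered subsets.
rarefy_bruteforce <- function(counts, n) {
  labels <- rep(seq_along(counts), times = counts)
  subsets <- utils::combn(length(labels), n)
  mean(apply(subsets, 2L, function(ix) length(unique(labels[ix]))))
}

# Probability of interspecific encounter: enumerate every ordered pair of
# distinct individuals and count how often the two belong to different
# species. Counts are integers, so the quotient is exact.
pie_enumeration <- function(counts) {
  labels <- rep(seq_along(counts), times = counts)
  N <- length(labels)
  diff_pairs <- sum(outer(labels, labels, "!="))  # a == b never differs
  diff_pairs / (N * (N - 1))
}

# All multisets of positive species abundances with a given total (integer
# partitions; the metrics are symmetric in species identity).
partitions_of <- function(total, max_part = total) {
  if (total == 0L) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(total, max_part))) {
    for (rest in partitions_of(total - first, first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Small fixed community: 2 sites x 2 managements x 2 plots x 3 subplots.
make_toy_table <- function(seed = 99, lambda = 40, S = 12) {
  set.seed(seed)
  n_sub <- 3L
  rows <- list(); meta <- list()
  for (site in c("A", "B")) for (mg in c("pasture", "meadow")) for (pl in 1:2) {
    for (sb in seq_len(n_sub)) {
      rows[[length(rows) + 1L]] <- stats::rmultinom(1L, stats::rpois(1L, lambda),
                                                    rep(1 / S, S))[, 1L]
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = paste(site, mg, pl, sb, sep = "_"),
        site = site, plot = paste0(mg, pl), subplot = paste0("s", sb),
        management = mg, lui_category = "none", stringsAsFactors = FALSE)
    }
  }
  community_table(do.call(rbind, rows), do.call(rbind, meta),
                  taxa = sprintf("t%02d", seq_len(S)), abundance_kind = "counts")
}

# A site whose two management groups are identical multisets of subplots:
# the exact null by construction.
make_duplicate_group_table <- function(seed = 7, n_sub = 6, lambda = 30, S = 8) {
  set.seed(seed)
  half <- t(sapply(seq_len(n_sub), function(i)
    stats::rmultinom(1L, stats::rpois(1L, lambda), rep(1 / S, S))[, 1L]))
  meta <- do.call(rbind, lapply(c("pasture", "meadow"), function(mg)
    data.frame(sample_id = paste(mg, seq_len(n_sub), sep = "_"),
               site = "dup", plot = paste0(mg, rep(1:2, each = n_sub / 2)),
               subplot = paste0("s", seq_len(n_sub)), management = mg,
               lui_category = "none", stringsAsFactors = FALSE)))
  community_table(rbind(half, half), meta,
                  taxa = sprintf("t%02d", seq_len(S)), abundance_kind = "counts")
}
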