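## Independent oracles used by unit and acceptance tests. These re-derive
## expected results by enumeration/simulation and must stay independent of
## the package's own implementations.

library(data.table)

## Brute-force clan-overlap oracle: enumerate all subsets of contested
## (non-MCE, clanned) hits and return the unique maximal valid subset.
## Valid means: (1) no two retained non-MCE hits of the same clan overlap;
## (2) every removed hit overlaps a retained non-MCE same-clan hit of
## strictly higher priority (bit score desc, start asc, name asc). MCE hits
## are exempt from conflicts in both directions: restricting justification
## to non-MCE clan-mates is what makes the maximal subset unique.
oracle_resolve <- function(hits) {
  stopifnot(nrow(hits) <= 10L)
  contested <- which(!hits$is_mce & !is.na(hits$clan_id))
  always <- setdiff(seq_len(nrow(hits)), contested)
  overlaps <- function(i, j) {
    hits$start[i] <= hits$end[j] & hits$end[i] >= hits$start[j] &
      !is.na(hits$clan_id[i]) & !is.na(hits$clan_id[j]) &
      hits$clan_id[i] == hits$clan_id[j]
  }
  prio <- order(-hits$bit_score, hits$start, hits$domain_name)
  rank <- match(seq_len(nrow(hits)), prio)   # smaller = higher priority
  valid_subsets <- list()
  n <- length(contested)
  for (mask in 0:(2^n - 1L)) {
    inb <- contested[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    outb <- setdiff(contested, inb)
    retained <- c(always, inb)
    ok <- TRUE
    if (length(inb) > 1L) {
      prs <- utils::combn(inb, 2L)
      for (k in seq_len(ncol(prs))) {
        if (overlaps(prs[1L, k], prs[2L, k])) { ok <- FALSE; break }
      }
    }
    if (ok) for (h in outb) {
      just <- any(vapply(inb, function(k) {
        overlaps(h, k) && rank[k] < rank[h]
      }, logical(1)))
      if (!just) { ok <- FALSE; break }
    }
    if (ok) valid_subsets[[length(valid_subsets) + 1L]] <- sort(retained)
  }
  ## maximal by inclusion; the spec asserts uniqueness
  maximal <- Filter(function(s) {
    !any(vapply(valid_subsets, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, valid_subsets)
  maximal <- unique(maximal)
  stopifnot(length(maximal) == 1L)
  hits[maximal[[1L]]][order(start, -bit_score, domain_name)]
}

## Random hit set for one protein (continuous bit scores: no ties).
random_hits <- function(n_hits, p_mce = 0.25, p_clan = 0.7) {
  starts <- sample.int(300L, n_hits, replace = TRUE)
  lens <- sample(30:120, n_hits, replace = TRUE)
  is_mce <- runif(n_hits) < p_mce
  name <- ifelse(is_mce, "MCE",
                 sample(paste0("DOM", 1:4), n_hits, replace = TRUE))
  clan <- ifelse(runif(n_hits) < p_clan,
                 sample(c("CLA", "CLB"), n_hits, replace = TRUE),
                 NA_character_)
  data.table(protein_id = "p1", domain_name = name, clan_id = clan,
             start = starts, end = starts + lens,
             bit_score = runif(n_hits, 10, 100),
             e_value = 10^-runif(n_hits, 1, 20),
             is_mce = name == "MCE")
}

## Order-respecting reference for greedy longest-first clustering:
## a literal simulation over a dense identity matrix.
oracle_greedy <- function(proteins, identities, threshold) {
  ord <- proteins$protein_id[order(-proteins$length, proteins$protein_id)]
  pct <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
  for (r in seq_len(nrow(identities))) {
    q <- identities$query_id[r]; s <- identities$subject_id[r]
    if (q == s) next
    v <- identities$pct_identity[r]
    pct[q, s] <- max(pct[q, s], v)
    pct[s, q] <- max(pct[s, q], v)
  }
  reps <- character(0)
  assignment <- setNames(character(length(ord)), ord)
  for (p in ord) {
    found <- NA_character_
    for (rp in reps) {
      if (pct[p, rp] / 100 >= threshold) { found <- rp; break }
    }
    if (is.na(found)) {
      reps <- c(reps, p); assignment[p] <- p
    } else {
      assignment[p] <- found
    }
  }
  assignment
}

## Adjusted Rand Index between two labelings (closed form).
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
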