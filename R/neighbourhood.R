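## neighbourhood module: slot-indexed gene neighbourhoods around MCE genes,
## centre-weighted similarity, nearest-neighbour agglomeration, summaries.

SLOT_NAMES <- c(paste0("-", 10:1), paste0("+", 1:10))

#' Centre-weighted slot weights
#'
#' Genes closer to the focal gene are weighted more: slot i carries weight
#' `r^(|i| - 1)`, so the immediate neighbours (slots +-1) have weight 1 and
#' weights decay geometrically outwards.
#'
#' @param r Decay ratio in (0, 1]; default 0.5.
#' @return A `neighbourhood_weights` object.
#' @export
neighbourhood_weights <- function(r = 0.5) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    config_error("weight decay ratio r must lie in (0, 1], got ", r)
  }
  w <- r^(abs(as.integer(sub("\\+", "", SLOT_NAMES))) - 1)
  structure(list(r = r, w = setNames(w, SLOT_NAMES)),
            class = "neighbourhood_weights")
}

#' Extract the gene neighbourhood around one focal MCE gene
#'
#' Takes up to `max_genes` genes on each side of the focal gene, in order of
#' increasing distance, discarding genes whose nearest boundary lies more
#' than `window_bp` from the focal gene's nearest boundary. Genes on other
#' contigs or genomes are never included. Each slot holds the canonical
#' architecture string of the encoded protein; genes without a significant
#' domain (or without a protein) get `"NONE"`. If the focal gene is on the
#' minus strand the two sides are swapped, so negative slots are always
#' upstream of the focal gene's reading direction.
#'
#' @param loci Gene locus table ([read_gff()] layout).
#' @param focal_gene_id Gene id of the focal MCE gene (must be in `loci`).
#' @param arch_strings Named character vector: protein_id -> canonical
#'   architecture string.
#' @param focal_type Type label recorded on the neighbourhood.
#' @param window_bp Window half-width in bp (default 10000).
#' @param max_genes Maximum genes per side (default 10).
#' @return An object of class `mce_neighbourhood`: `focal_gene`,
#'   `focal_type`, `slots` (named character of length 20, `NA` = absent),
#'   `orientation_normalized = TRUE`.
#' @export
extract_neighbourhood <- function(loci, focal_gene_id, arch_strings,
                                  focal_type = NA_character_,
                                  window_bp = 10000L, max_genes = 10L) {
  focal <- loci[gene_id == focal_gene_id]
  if (nrow(focal) != 1L) {
    stop_mce("extract_neighbourhood: focal gene '", focal_gene_id,
             "' matches ", nrow(focal), " loci; expected exactly one")
  }
  nbr <- loci[genome_id == focal$genome_id & contig == focal$contig &
                gene_id != focal_gene_id]
  slots <- setNames(rep(NA_character_, 20L), SLOT_NAMES)
  if (nrow(nbr)) {
    nbr <- copy(nbr)
    nbr[, gap := fifelse(end < focal$start, focal$start - end,
                         fifelse(start > focal$end, start - focal$end, 0L))]
    nbr[, midpoint := (start + end) / 2]
    nbr[, side := fifelse(midpoint < (focal$start + focal$end) / 2,
                          "left", "right")]
    nbr <- nbr[gap <= window_bp]
    lookup <- function(pid) {
      if (is.na(pid) || !pid %in% names(arch_strings)) return("NONE")
      a <- arch_strings[[pid]]
      if (is.na(a) || !nzchar(a)) "NONE" else a
    }
    left <- nbr[side == "left"][order(gap, -end, gene_id)]
    right <- nbr[side == "right"][order(gap, start, gene_id)]
    nl <- min(nrow(left), max_genes)
    nr <- min(nrow(right), max_genes)
    if (nl) slots[paste0("-", 1:nl)] <- vapply(left$protein_id[1:nl],
                                               lookup, character(1))
    if (nr) slots[paste0("+", 1:nr)] <- vapply(right$protein_id[1:nr],
                                               lookup, character(1))
  }
  if (focal$strand == "-") {
    flipped <- setNames(rep(NA_character_, 20L), SLOT_NAMES)
    flipped[paste0("-", 1:10)] <- slots[paste0("+", 1:10)]
    flipped[paste0("+", 1:10)] <- slots[paste0("-", 1:10)]
    slots <- flipped
  }
  structure(list(focal_gene = focal_gene_id, focal_type = focal_type,
                 slots = slots, orientation_normalized = TRUE),
            class = "mce_neighbourhood")
}

#' Extract neighbourhoods for every focal MCE gene of given types
#'
#' @param loci Gene locus table.
#' @param architectures Architecture table from [build_architectures()].
#' @param types Focal architecture types to analyse (default I, III, IV).
#' @param synonym_map Applied to neighbour architecture strings.
#' @inheritParams extract_neighbourhood
#' @return A list of `mce_neighbourhood` objects.
#' @export
extract_neighbourhoods <- function(loci, architectures,
                                   types = c("I", "III", "IV"),
                                   synonym_map = default_synonym_map(),
                                   window_bp = 10000L, max_genes = 10L) {
  arch_strings <- setNames(merge_synonyms(architectures$domains, synonym_map),
                           architectures$protein_id)
  typed <- architectures[type_label %in% types]
  focal <- loci[protein_id %in% typed$protein_id]
  type_of <- setNames(typed$type_label, typed$protein_id)
  lapply(seq_len(nrow(focal)), function(i) {
    extract_neighbourhood(loci, focal$gene_id[i], arch_strings,
                          focal_type = type_of[[focal$protein_id[i]]],
                          window_bp = window_bp, max_genes = max_genes)
  })
}

#' Centre-weighted similarity between two neighbourhoods
#'
#' Over the slots occupied in either neighbourhood, the similarity is the
#' weight-normalised fraction of agreeing slots:
#' `S(a, b) = sum_i w(i) [a_i == b_i] / sum_i w(i)` with the sum over slots
#' occupied in a or b; a present-vs-absent slot counts as a mismatch.
#' Symmetric, bounded in `[0, 1]`; `S(a, a) = 1`.
#'
#' @param a,b `mce_neighbourhood` objects (orientation-normalized).
#' @param weights A [neighbourhood_weights()] object.
#' @return Similarity in `[0, 1]`.
#' @export
neighbourhood_similarity <- function(a, b,
                                     weights = neighbourhood_weights()) {
  stopifnot(inherits(a, "mce_neighbourhood"),
            inherits(b, "mce_neighbourhood"),
            inherits(weights, "neighbourhood_weights"))
  if (!isTRUE(a$orientation_normalized) ||
      !isTRUE(b$orientation_normalized)) {
    stop_mce("neighbourhood_similarity: inputs must be ",
             "orientation-normalized")
  }
  occ <- !is.na(a$slots) | !is.na(b$slots)
  if (!any(occ)) return(1)
  agree <- !is.na(a$slots) & !is.na(b$slots) & a$slots == b$slots
  sum(weights$w[occ & agree]) / sum(weights$w[occ])
}

pairwise_similarity_matrix <- function(neighbourhoods, weights) {
  n <- length(neighbourhoods)
  slot_mat <- vapply(neighbourhoods, function(nb) nb$slots,
                     character(length(SLOT_NAMES)))
  s <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ai <- slot_mat[, i]
      for (j in seq.int(i + 1L, n)) {
        bj <- slot_mat[, j]
        occ <- !is.na(ai) | !is.na(bj)
        val <- if (!any(occ)) 1 else {
          agree <- !is.na(ai) & !is.na(bj) & ai == bj
          sum(weights$w[occ & agree]) / sum(weights$w[occ])
        }
        s[i, j] <- s[j, i] <- val
      }
    }
  }
  s
}

#' Agglomerative nearest-neighbour clustering of neighbourhoods
#'
#' Repeatedly merges the pair of clusters with the highest inter-cluster
#' similarity (single linkage by default) until the best remaining similarity
#' falls below `tau`, recording every merge. Ties are broken by the
#' lexicographically smallest (min cluster id, max cluster id) pair; a
#' cluster's id is the smallest focal-gene id among its members.
#'
#' @param neighbourhoods List of `mce_neighbourhood` objects, all with the
#'   same `focal_type`.
#' @param weights A [neighbourhood_weights()] object.
#' @param tau Stop threshold in `[0, 1]`; merges require similarity `>= tau`.
#' @param linkage `"single"` (default), `"complete"` or `"average"`.
#' @return A list of class `neighbourhood_clustering`: `assignments`
#'   (`data.table` focal_gene, cluster), `merges` (`data.table` step,
#'   cluster_a, cluster_b, similarity), `tau`, `linkage`.
#' @export
cluster_neighbourhoods <- function(neighbourhoods,
                                   weights = neighbourhood_weights(),
                                   tau = 0.5, linkage = "single") {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    config_error("stop threshold tau must lie in [0, 1], got ", tau)
  }
  linkage <- match.arg(linkage, c("single", "complete", "average"))
  if (length(neighbourhoods) == 0L) {
    stop_mce("cluster_neighbourhoods: need at least one neighbourhood")
  }
  types <- unique(vapply(neighbourhoods, `[[`, character(1), "focal_type"))
  if (length(types) > 1L) {
    stop_mce("cluster_neighbourhoods: mixed focal types (",
             paste(types, collapse = ", "), "); cluster each type separately")
  }
  ids <- vapply(neighbourhoods, `[[`, character(1), "focal_gene")
  s <- pairwise_similarity_matrix(neighbourhoods, weights)
  members <- as.list(seq_along(ids))
  cl_id <- ids
  link_fun <- switch(linkage, single = max, complete = min, average = mean)
  merges <- list()
  step <- 0L
  repeat {
    k <- length(members)
    if (k < 2L) break
    best <- -Inf; best_pair <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        val <- link_fun(s[members[[i]], members[[j]]])
        lo <- min(cl_id[i], cl_id[j]); hi <- max(cl_id[i], cl_id[j])
        if (val > best ||
            (val == best && (lo < best_pair$lo ||
                             (lo == best_pair$lo && hi < best_pair$hi)))) {
          best <- val
          best_pair <- list(i = i, j = j, lo = lo, hi = hi)
        }
      }
    }
    if (best < tau) break
    step <- step + 1L
    merges[[step]] <- data.table(step = step, cluster_a = best_pair$lo,
                                 cluster_b = best_pair$hi, similarity = best)
    members[[best_pair$i]] <- c(members[[best_pair$i]],
                                members[[best_pair$j]])
    cl_id[best_pair$i] <- best_pair$lo
    members[[best_pair$j]] <- NULL
    cl_id <- cl_id[-best_pair$j]
  }
  assignments <- rbindlist(lapply(seq_along(members), function(i) {
    data.table(focal_gene = ids[members[[i]]], cluster = cl_id[i])
  }))
  setorder(assignments, focal_gene)
  merges <- if (step) rbindlist(merges) else
    data.table(step = integer(), cluster_a = character(),
               cluster_b = character(), similarity = numeric())
  structure(list(assignments = assignments, merges = merges, tau = tau,
                 linkage = linkage),
            class = "neighbourhood_clustering")
}

#' Summarise clustered neighbourhoods per focal type
#'
#' For each cluster: the number of members, the percentage of all focal
#' genes of the type (`100 * members / total`), and a consensus pattern
#' giving the majority architecture per slot among members occupying that
#' slot (lexicographic tie-break); slots occupied by fewer than half the
#' members stay absent in the consensus only if no member occupies them.
#'
#' @param clustering A `neighbourhood_clustering`.
#' @param neighbourhoods The clustered `mce_neighbourhood` list.
#' @param total Denominator: total focal genes of this type (defaults to
#'   `length(neighbourhoods)`).
#' @return A `data.table`, one row per cluster ordered by descending size:
#'   `cluster`, `n_members`, `percentage`, one column per slot with the
#'   consensus architecture (`NA` = absent in all members).
#' @export
summarise_neighbourhoods <- function(clustering, neighbourhoods,
                                     total = length(neighbourhoods)) {
  ids <- vapply(neighbourhoods, `[[`, character(1), "focal_gene")
  slot_mat <- vapply(neighbourhoods, function(nb) nb$slots,
                     character(length(SLOT_NAMES)))
  asg <- clustering$assignments
  rows <- lapply(split(asg$focal_gene, asg$cluster), function(mem) {
    cols <- slot_mat[, match(mem, ids), drop = FALSE]
    consensus <- apply(cols, 1L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      tab <- table(x)
      names(tab)[order(-tab, names(tab))][1L]
    })
    c(list(n_members = length(mem)), as.list(consensus))
  })
  out <- rbindlist(lapply(names(rows), function(cl) {
    as.data.table(c(list(cluster = cl), rows[[cl]]))
  }))
  out[, percentage := 100 * n_members / total]
  setorder(out, -n_members, cluster)
  setcolorder(out, c("cluster", "n_members", "percentage", SLOT_NAMES))
  out[]
}

#' @rdname summarise_neighbourhoods
#' @param neighbourhood_summary Table from [summarise_neighbourhoods()].
#' @param path TSV path.
#' @export
write_neighbourhood_summary <- function(neighbourhood_summary, path) {
  fwrite(neighbourhood_summary, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Flatten neighbourhoods to a slot table
#'
#' @param neighbourhoods List of `mce_neighbourhood` objects.
#' @return `data.table` with `focal_gene`, `focal_type` and one column per
#'   slot (-10..+10).
#' @export
neighbourhood_table <- function(neighbourhoods) {
  rbindlist(lapply(neighbourhoods, function(nb) {
    as.data.table(c(list(focal_gene = nb$focal_gene,
                         focal_type = nb$focal_type),
                    as.list(nb$slots)))
  }))
}
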