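## architecture module: from per-protein domain hits to one ordered
## architecture and the type I-IV classification.

#' Per-family significance thresholds (Pfam gathering-score analogue)
#'
#' @param thresholds Named numeric vector mapping domain name to its minimum
#'   bit score; families not listed fall back to `default_threshold`.
#' @param default_threshold Bit-score floor for unlisted families.
#' @return A `threshold_table` object.
#' @export
threshold_table <- function(thresholds = numeric(), default_threshold = 25) {
  if (length(thresholds) && is.null(names(thresholds))) {
    config_error("threshold_table: 'thresholds' must be named by domain")
  }
  if (!all(is.finite(c(thresholds, default_threshold)))) {
    config_error("threshold_table: thresholds must be finite")
  }
  structure(list(thresholds = thresholds,
                 default_threshold = default_threshold),
            class = "threshold_table")
}

get_threshold <- function(tt, domain_name) {
  stopifnot(inherits(tt, "threshold_table"))
  out <- rep(tt$default_threshold, length(domain_name))
  hit <- match(domain_name, names(tt$thresholds))
  out[!is.na(hit)] <- tt$thresholds[hit[!is.na(hit)]]
  out
}

#' Keep hits at or above their family's gathering threshold
#'
#' @param hits Domain hit table ([read_domain_hits()] layout).
#' @param thresholds A [threshold_table()].
#' @return The significant subset, input order preserved.
#' @export
filter_significant <- function(hits, thresholds) {
  if (nrow(hits) == 0L) return(hits)
  hits[bit_score >= get_threshold(thresholds, domain_name)]
}

## Priority order used for all score tie-breaks: higher bit score first,
## then smaller start, then lexicographically smaller domain name.
hit_priority_order <- function(hits) {
  order(-hits$bit_score, hits$start, hits$domain_name)
}

#' Resolve overlapping same-clan predictions for one protein
#'
#' Overlapping hits (>= 1 shared residue, closed intervals) from the same Pfam
#' clan are redundant predictions of a single region: only the most
#' significant survives. The resolution is greedy in descending bit score
#' (ties: smaller start, then name): a non-MCE hit is discarded iff it
#' overlaps an already-retained non-MCE hit of the same clan. MCE hits are
#' never removed and never cause a removal; clanless hits never conflict.
#' This equals the unique maximal hit subset in which no two retained non-MCE
#' same-clan hits overlap and every removal is justified by a retained
#' higher-priority overlapping clan-mate.
#'
#' @param hits Hit table for a single protein.
#' @return The surviving hits, sorted by start position.
#' @export
resolve_clan_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  if (uniqueN(hits$protein_id) > 1L) {
    stop_mce("resolve_clan_overlaps: hits span ",
             uniqueN(hits$protein_id), " proteins; expected exactly one")
  }
  contested <- !hits$is_mce & !is.na(hits$clan_id)
  if (sum(contested) <= 1L) {
    return(hits[order(start, -bit_score, domain_name)])
  }
  cand <- hits[contested][hit_priority_order(hits[contested])]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(kept[seq_len(i - 1L)])
    clash <- length(prior) > 0L && any(
      cand$clan_id[prior] == cand$clan_id[i] &
        cand$start[prior] <= cand$end[i] &
        cand$end[prior] >= cand$start[i]
    )
    kept[i] <- !clash
  }
  out <- rbind(hits[!contested], cand[kept])
  out[order(start, -bit_score, domain_name)]
}

#' Resolve clan overlaps across a whole hit table
#'
#' Applies [resolve_clan_overlaps()] per protein. Proteins with at most one
#' clanned non-MCE hit are passed through untouched (the common case).
#'
#' @param hits Hit table for any number of proteins.
#' @return Resolved hit table, sorted by (protein_id, start).
#' @export
resolve_clan_overlaps_all <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  contested <- hits[!is_mce & !is.na(clan_id), .N, by = protein_id][N > 1L]
  easy <- hits[!protein_id %in% contested$protein_id]
  hard <- hits[protein_id %in% contested$protein_id]
  if (nrow(hard)) {
    hard <- hard[, resolve_clan_overlaps(.SD), by = protein_id,
                 .SDcols = setdiff(names(hits), "protein_id")]
    setcolorder(hard, names(hits))
  }
  out <- rbind(easy, hard)
  setorder(out, protein_id, start, -bit_score, domain_name)
  out[]
}

#' Classify an ordered domain architecture into the MCE type scheme
#'
#' Types: I = a single MCE domain and nothing else; II = one MCE followed by
#' one DUF3407 and nothing else; III = exactly three MCE domains in tandem
#' (consecutive, no intervening domain) and nothing else; IV = exactly seven.
#' Any other architecture containing an MCE domain is `other_mce`; an
#' architecture with no MCE domain is `non_mce`.
#'
#' @param domains Character vector of domain names in start-position order.
#' @param mce_family,duf3407_family Family names used by the scheme.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"other_mce"`, `"non_mce"`.
#' @export
classify_type <- function(domains, mce_family = "MCE",
                          duf3407_family = "DUF3407") {
  n_mce <- sum(domains == mce_family)
  if (n_mce == 0L) return("non_mce")
  if (identical(domains, mce_family)) return("I")
  if (identical(domains, c(mce_family, duf3407_family))) return("II")
  if (length(domains) == 3L && n_mce == 3L) return("III")
  if (length(domains) == 7L && n_mce == 7L) return("IV")
  "other_mce"
}

#' Build one protein's architecture from resolved hits
#'
#' @param hits Filtered, overlap-resolved hits for one protein (may be empty).
#' @param protein_id Protein identifier (required when `hits` is empty).
#' @param mce_family,duf3407_family Family names for [classify_type()].
#' @return A list with `protein_id`, `domains` (start-ordered), `mce_count`,
#'   `type_label`.
#' @export
build_architecture <- function(hits, protein_id = NULL, mce_family = "MCE",
                               duf3407_family = "DUF3407") {
  pid <- protein_id %||% if (nrow(hits)) hits$protein_id[1L] else
    stop_mce("build_architecture: protein_id required for empty hit set")
  doms <- if (nrow(hits)) {
    hits$domain_name[order(hits$start, -hits$bit_score, hits$domain_name)]
  } else character()
  list(protein_id = pid, domains = doms,
       mce_count = sum(doms == mce_family),
       type_label = classify_type(doms, mce_family, duf3407_family))
}

#' Validate an architecture synonym map
#'
#' The map sends architecture strings to canonical architecture strings
#' (e.g. `"ABC_tran, AAA_21"` to `"ABC_tran"`). To guarantee idempotence any
#' value that is also a key must map to itself.
#'
#' @param synonym_map Named character vector (names = raw, values =
#'   canonical), or NULL/empty for the identity map.
#' @return The validated map (possibly empty), invisibly usable downstream.
#' @export
validate_synonym_map <- function(synonym_map) {
  if (is.null(synonym_map) || length(synonym_map) == 0L) {
    return(setNames(character(), character()))
  }
  synonym_map <- unlist(synonym_map)
  if (is.null(names(synonym_map)) || any(!nzchar(names(synonym_map)))) {
    config_error("synonym_map entries must be named by the raw architecture")
  }
  chained <- synonym_map[synonym_map %in% names(synonym_map) &
                           synonym_map != names(synonym_map)]
  resolved <- synonym_map[match(chained, names(synonym_map))]
  if (any(resolved != chained)) {
    config_error("synonym_map is cyclic or chained: ",
                 paste(names(chained)[resolved != chained], collapse = ", "),
                 " maps to a value that is itself remapped")
  }
  synonym_map
}

#' Canonicalise architecture strings through the synonym map
#'
#' Unmapped strings pass through unchanged; the operation is idempotent.
#'
#' @param arch_names Character vector of architecture strings.
#' @param synonym_map Map validated by [validate_synonym_map()].
#' @return Canonical architecture strings.
#' @export
merge_synonyms <- function(arch_names, synonym_map = default_synonym_map()) {
  synonym_map <- validate_synonym_map(synonym_map)
  hit <- match(arch_names, names(synonym_map))
  out <- arch_names
  out[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  out
}

#' The default architecture synonym map
#'
#' Merges the bare ABC-transporter ATPase architecture with its AAA_21
#' double-annotation variant, which describe the same gene product.
#'
#' @return Named character vector.
#' @export
default_synonym_map <- function() {
  c("ABC_tran, AAA_21" = "ABC_tran")
}

#' Build the architecture table for a whole dataset
#'
#' Runs gathering-threshold filtering, clan-overlap resolution, start-position
#' ordering and type classification for every protein. Proteins present in
#' `proteins` but without a single significant hit are reported with an empty
#' architecture and type `non_mce`.
#'
#' @param hits Raw domain hit table.
#' @param proteins Protein metadata table (or NULL to cover only proteins with
#'   hits).
#' @param thresholds A [threshold_table()].
#' @param mce_family,duf3407_family Family names of the classification scheme.
#' @param synonym_map Architecture synonym map applied to the final strings.
#' @return A `data.table` with `protein_id`, `type_label`, `mce_count`,
#'   `domains` (comma-joined canonical architecture string, `""` for none).
#' @export
build_architectures <- function(hits, proteins = NULL,
                                thresholds = threshold_table(),
                                mce_family = "MCE",
                                duf3407_family = "DUF3407",
                                synonym_map = default_synonym_map()) {
  synonym_map <- validate_synonym_map(synonym_map)
  sig <- filter_significant(hits, thresholds)
  res <- resolve_clan_overlaps_all(sig)
  if (nrow(res)) {
    archs <- res[order(protein_id, start, -bit_score, domain_name),
                 .(domains = arch_string(domain_name),
                   mce_count = sum(domain_name == mce_family),
                   type_label = classify_type(domain_name, mce_family,
                                              duf3407_family)),
                 by = protein_id]
  } else {
    archs <- data.table(protein_id = character(), domains = character(),
                        mce_count = integer(), type_label = character())
  }
  if (!is.null(proteins)) {
    missing <- setdiff(proteins$protein_id, archs$protein_id)
    if (length(missing)) {
      archs <- rbind(archs, data.table(
        protein_id = missing, domains = "", mce_count = 0L,
        type_label = "non_mce"))
    }
  }
  archs[, domains := merge_synonyms(domains, synonym_map)]
  setorder(archs, protein_id)
  setcolorder(archs, c("protein_id", "type_label", "mce_count", "domains"))
  archs[]
}

#' @rdname build_architectures
#' @param architectures Architecture table.
#' @param path TSV path.
#' @export
write_architectures <- function(architectures, path) {
  fwrite(architectures, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname build_architectures
#' @export
read_architectures <- function(path) {
  fread(path, sep = "\t", header = TRUE,
        colClasses = list(character = c("protein_id", "type_label",
                                        "domains"),
                          integer = "mce_count"))[]
}
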