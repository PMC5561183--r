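## prevalence module: phylum x architecture-type presence percentages over
## one representative genome per species.

#' Pick one representative genome per species
#'
#' Databases over-represent well-studied species with many sequenced strains;
#' prevalence is therefore computed over a single genome per species, chosen
#' uniformly at random. The choice is deterministic for a fixed seed.
#'
#' @param proteins Protein metadata table with `species_id` and `genome_id`.
#' @param seed Integer seed for the random picks.
#' @return Named character vector: `species_id` -> chosen `genome_id`.
#' @export
select_representative_genomes <- function(proteins, seed = 1L) {
  pairs <- unique(proteins[, .(species_id, genome_id)])
  setorder(pairs, species_id, genome_id)
  with_seed(seed, {
    picks <- pairs[, .(genome_id = genome_id[sample.int(.N, 1L)]),
                   by = species_id]
  })
  setNames(picks$genome_id, picks$species_id)
}

#' Phylum-by-type prevalence matrix
#'
#' A species counts as positive for an architecture type iff its
#' representative genome encodes at least one protein of that type. The
#' phylum percentage is 100 * positives / species_total, where the
#' denominator counts every species of the phylum present in `proteins`
#' (species without any MCE protein included). Phyla with zero species do not
#' appear.
#'
#' @param architectures Architecture table from [build_architectures()].
#' @param proteins Protein metadata table.
#' @param representative_map Output of [select_representative_genomes()];
#'   must cover every species in `proteins`.
#' @param types Type labels forming the matrix columns.
#' @return A `data.table` with `phylum`, `species_total` and one percentage
#'   column per type, phyla sorted alphabetically.
#' @export
compute_prevalence <- function(architectures, proteins, representative_map,
                               types = c("I", "II", "III", "IV")) {
  missing_species <- setdiff(unique(proteins$species_id),
                             names(representative_map))
  if (length(missing_species)) {
    stop_mce("compute_prevalence: no representative genome for species ",
             paste(head(missing_species, 5L), collapse = ", "))
  }
  unknown <- setdiff(architectures$protein_id, proteins$protein_id)
  if (length(unknown)) {
    stop_mce("compute_prevalence: architecture references unknown ",
             "protein(s): ", paste(head(unknown, 5L), collapse = ", "))
  }
  species <- unique(proteins[, .(species_id, phylum)])
  if (anyDuplicated(species$species_id)) {
    stop_mce("compute_prevalence: species assigned to multiple phyla")
  }
  rep_prot <- proteins[genome_id == representative_map[species_id]]
  typed <- architectures[rep_prot, on = "protein_id", nomatch = NULL][
    type_label %in% types,
    unique(.SD), .SDcols = c("species_id", "phylum", "type_label")]
  out <- species[, .(species_total = .N), by = phylum]
  for (ty in types) {
    pos <- typed[type_label == ty, .(positives = uniqueN(species_id)),
                 by = phylum]
    out[, (ty) := 0]
    out[pos, (ty) := 100 * i.positives / species_total,
        on = "phylum"]
  }
  setorder(out, phylum)
  out[]
}

#' Flag MCE proteins recorded in non-bacterial genomes
#'
#' MCE domains found in eukaryotic assemblies are frequently bacterial-DNA
#' contamination. This automates the screen up to flagging: every
#' MCE-containing protein whose metadata is not bacterial is emitted for
#' manual review; nothing is removed automatically.
#'
#' @param architectures Architecture table.
#' @param proteins Protein metadata table with `superkingdom`.
#' @return A `data.table` of flagged proteins (`protein_id`, `species_id`,
#'   `phylum`, `superkingdom`, `type_label`).
#' @export
flag_suspect_eukaryote_hits <- function(architectures, proteins) {
  mce <- architectures[mce_count > 0L]
  flagged <- proteins[mce, on = "protein_id", nomatch = NULL][
    tolower(superkingdom) != "bacteria",
    .(protein_id, species_id, phylum, superkingdom, type_label)]
  setorder(flagged, protein_id)
  flagged[]
}

#' @rdname compute_prevalence
#' @param prevalence Prevalence table.
#' @param path TSV path.
#' @export
write_prevalence <- function(prevalence, path) {
  fwrite(prevalence, path, sep = "\t", quote = FALSE)
  invisible(path)
}
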