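## Small in-code fixtures shared across test files.

make_hit <- function(protein_id = "p1", domain_name = "MCE",
                     clan_id = NA_character_, start = 1L, end = 81L,
                     bit_score = 50, e_value = 1e-10,
                     mce_family = "MCE") {
  data.table(protein_id = protein_id, domain_name = domain_name,
             clan_id = clan_id, start = as.integer(start),
             end = as.integer(end), bit_score = bit_score,
             e_value = e_value, is_mce = domain_name == mce_family)
}

make_locus <- function(gene_id, start, end, strand = "+",
                       protein_id = NA_character_, genome_id = "g1",
                       contig = "c1") {
  data.table(gene_id = gene_id, genome_id = genome_id, contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, protein_id = protein_id)
}

make_neighbourhood <- function(focal_gene, slots, focal_type = "I") {
  full <- setNames(rep(NA_character_, 20L),
                   c(paste0("-", 10:1), paste0("+", 1:10)))
  full[names(slots)] <- slots
  structure(list(focal_gene = focal_gene, focal_type = focal_type,
                 slots = full, orientation_normalized = TRUE),
            class = "mce_neighbourhood")
}

fixture_path <- function(name) testthat::test_path("fixtures", name)
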