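## io module: readers/writers for every external format the pipeline touches.
## Coordinates are 1-based inclusive everywhere (HMMER/GFF3 convention).

#' Read a per-domain hit table (HMMER domtblout or the 7-column dialect)
#'
#' Accepts two whitespace-delimited dialects, distinguished per line by field
#' count:
#' \itemize{
#'   \item real `hmmsearch --domtblout` output (>= 22 fields): target name
#'     becomes `protein_id`, query (HMM) name becomes `domain_name`, envelope
#'     coordinates become `start`/`end`, and the domain independent e-value
#'     (column 13) and domain bit score (column 14) are used. Pfam clan ids are
#'     not present in domtblout, so `clan_id` is `NA`.
#'   \item the package's own 7-column dialect
#'     (`protein_id domain_name clan_id env_from env_to bit_score i_evalue`,
#'     clan `-` for clanless families), as written by [write_domain_hits()]
#'     and the simulator.
#' }
#' Lines starting with `#` are comments; an empty file yields an empty table.
#'
#' @param path Path to the hit table.
#' @param mce_family Pfam family name of the MCE domain; hits whose
#'   `domain_name` equals it exactly get `is_mce = TRUE`.
#' @return A `data.table` with columns `protein_id`, `domain_name`, `clan_id`
#'   (`NA` when absent), `start`, `end` (1-based inclusive envelope residue
#'   coordinates), `bit_score`, `e_value`, `is_mce`.
#' @export
read_domain_hits <- function(path, mce_family = "MCE") {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  empty <- data.table(
    protein_id = character(), domain_name = character(),
    clan_id = character(), start = integer(), end = integer(),
    bit_score = numeric(), e_value = numeric(), is_mce = logical()
  )
  if (length(data_idx) == 0L) return(empty)

  fields <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  parse_line <- function(f, lineno) {
    if (length(f) >= 22L) {
      ## hmmsearch --domtblout layout (col 23+ is free-text description)
      vals <- list(protein_id = f[1L], domain_name = f[4L],
                   clan_id = NA_character_,
                   start = f[20L], end = f[21L],
                   bit_score = f[14L], e_value = f[13L])
    } else if (length(f) == 7L) {
      vals <- list(protein_id = f[1L], domain_name = f[2L],
                   clan_id = if (f[3L] == "-") NA_character_ else f[3L],
                   start = f[4L], end = f[5L],
                   bit_score = f[6L], e_value = f[7L])
    } else {
      parse_error("domain hit parse error at line ", lineno,
                  ": expected 7 or >=22 fields, got ", length(f))
    }
    num <- suppressWarnings(list(
      start = as.integer(vals$start), end = as.integer(vals$end),
      bit_score = as.numeric(vals$bit_score),
      e_value = as.numeric(vals$e_value)
    ))
    if (anyNA(unlist(num))) {
      parse_error("domain hit parse error at line ", lineno,
                  ": non-numeric coordinate or score")
    }
    if (num$start < 1L || num$end < num$start) {
      parse_error("domain hit parse error at line ", lineno,
                  ": invalid envelope coordinates ", num$start, "..", num$end)
    }
    if (num$e_value < 0) {
      parse_error("domain hit parse error at line ", lineno,
                  ": negative e-value")
    }
    data.table(protein_id = vals$protein_id, domain_name = vals$domain_name,
               clan_id = vals$clan_id, start = num$start, end = num$end,
               bit_score = num$bit_score, e_value = num$e_value)
  }
  hits <- rbindlist(Map(parse_line, fields, data_idx))
  hits[, is_mce := domain_name == mce_family]
  hits[]
}

#' Write domain hits in the 7-column dialect
#'
#' The output re-parses through [read_domain_hits()] field-for-field.
#'
#' @param hits Hit table as returned by [read_domain_hits()].
#' @param path Output path.
#' @export
write_domain_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# mcetools domain hits:",
                   "protein_id domain_name clan_id env_from env_to",
                   "bit_score i_evalue"), con)
  if (nrow(hits)) {
    out <- hits[, paste(protein_id, domain_name,
                        fifelse(is.na(clan_id), "-", clan_id),
                        start, end,
                        format(bit_score, trim = TRUE, digits = 15),
                        format(e_value, trim = TRUE, digits = 15),
                        sep = "\t")]
    writeLines(out, con)
  }
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Parsing is delegated to \pkg{rtracklayer}. Only rows of the configured
#' feature types are kept. Every kept row must carry an explicit strand
#' (`+`/`-`): neighbourhood orientation normalisation needs it.
#'
#' @param path GFF3 file.
#' @param feature_types GFF3 `type` values to keep (default gene/CDS).
#' @param protein_attribute Attribute key holding the encoded protein id.
#' @param genome_attribute Attribute key holding the genome id; rows lacking
#'   it fall back to `default_genome`.
#' @param default_genome Genome id used when the attribute is absent
#'   (default: file name without extension).
#' @return A `data.table` with columns `gene_id`, `genome_id`, `contig`,
#'   `start`, `end` (1-based inclusive bp), `strand`, `protein_id` (`NA` for
#'   non-coding rows), sorted by (genome_id, contig, start).
#' @export
read_gff <- function(path, feature_types = c("gene", "CDS"),
                     protein_attribute = "protein_id",
                     genome_attribute = "genome_id",
                     default_genome = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) parse_error("GFF3 parse error in ", path, ": ",
                                    conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gr)
  keep <- as.character(mc$type) %in% feature_types
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(data.table(gene_id = character(), genome_id = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein_id = character()))
  }
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands == "*")) {
    parse_error("strand required for neighbourhood orientation: ",
                sum(strands == "*"), " feature(s) in ", path,
                " have no strand")
  }
  gene_id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  if (anyNA(gene_id)) {
    parse_error("GFF3 parse error in ", path,
                ": every kept feature needs an ID attribute")
  }
  prot <- if (protein_attribute %in% names(mc)) {
    as.character(mc[[protein_attribute]])
  } else rep(NA_character_, length(gr))
  gnm <- if (genome_attribute %in% names(mc)) {
    as.character(mc[[genome_attribute]])
  } else rep(NA_character_, length(gr))
  fallback <- default_genome %||% sub("\\.[^.]*$", "", basename(path))
  gnm[is.na(gnm)] <- fallback
  loci <- data.table(
    gene_id = gene_id, genome_id = gnm,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = strands, protein_id = prot
  )
  setorder(loci, genome_id, contig, start)
  loci[]
}

#' Write gene loci as GFF3
#'
#' @param loci Locus table as returned by [read_gff()].
#' @param path Output path.
#' @param feature_type GFF3 `type` written for every row.
#' @export
write_gff <- function(loci, path, feature_type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand
  )
  S4Vectors::mcols(gr)$type <- feature_type
  S4Vectors::mcols(gr)$source <- "mcetools"
  S4Vectors::mcols(gr)$ID <- loci$gene_id
  S4Vectors::mcols(gr)$genome_id <- loci$genome_id
  S4Vectors::mcols(gr)$protein_id <- loci$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an all-vs-all alignment table (BLAST tabular, outfmt 6)
#'
#' 12 tab-separated columns in the standard BLAST `-outfmt 6` order. Self hits
#' are dropped when `drop_self`; duplicate (query, subject) pairs are collapsed
#' to the row with the lowest e-value.
#'
#' @param path Tabular file.
#' @param drop_self Drop rows with `query_id == subject_id` (default TRUE).
#' @return A `data.table` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_alignments <- function(path, drop_self = TRUE) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  aln <- fread(path, header = FALSE, sep = "\t",
               colClasses = list(character = 1:12), fill = FALSE)
  if (nrow(aln) == 0L) {
    aln <- as.data.table(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), cols))
    return(aln)
  }
  if (ncol(aln) != 12L) {
    parse_error("alignment parse error in ", path, ": expected 12 columns, ",
                "got ", ncol(aln))
  }
  setnames(aln, cols)
  for (numcol in cols[3:12]) {
    v <- suppressWarnings(as.numeric(aln[[numcol]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      parse_error("alignment parse error in ", path, " line ", bad,
                  ": non-numeric value in column ", numcol)
    }
    set(aln, j = numcol, value = v)
  }
  if (any(aln$pct_identity < 0 | aln$pct_identity > 100)) {
    parse_error("alignment parse error in ", path,
                ": percent identity outside [0, 100]")
  }
  if (any(aln$e_value < 0)) {
    parse_error("alignment parse error in ", path, ": negative e-value")
  }
  if (drop_self) aln <- aln[query_id != subject_id]
  ## collapse duplicate (q, s) pairs to the lowest e-value
  setorder(aln, query_id, subject_id, e_value)
  aln <- unique(aln, by = c("query_id", "subject_id"))
  aln[]
}

#' Write an alignment table in BLAST outfmt-6 layout
#'
#' @param aln Alignment table as returned by [read_alignments()].
#' @param path Output path.
#' @export
write_alignments <- function(aln, path) {
  fwrite(aln, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write protein metadata tables
#'
#' Plain TSV with header: `protein_id`, `genome_id`, `species_id`, `phylum`,
#' `superkingdom`, `length`.
#'
#' @param path TSV path.
#' @return `read_proteins()`: a `data.table`; protein ids must be unique and
#'   lengths positive.
#' @export
read_proteins <- function(path) {
  prot <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("protein_id", "genome_id", "species_id", "phylum",
                  "superkingdom"),
    integer = "length"))
  if (anyDuplicated(prot$protein_id)) {
    parse_error("protein table ", path, ": duplicated protein_id")
  }
  if (any(prot$length <= 0L)) {
    parse_error("protein table ", path, ": non-positive protein length")
  }
  prot[]
}

#' @rdname read_proteins
#' @param proteins Protein table.
#' @export
write_proteins <- function(proteins, path) {
  fwrite(proteins, path, sep = "\t", quote = FALSE)
  invisible(path)
}
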