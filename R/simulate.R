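## simulate module: complete synthetic datasets (taxonomy, proteins, domain
## hits, gene tables, alignments) with planted ground truth, so every
## pipeline stage is testable offline. No amino-acid sequences are
## generated; scores, identities and e-values are planted directly.

BACTERIAL_PHYLA <- c(
  "Aquificae", "Actinobacteria", "Proteobacteria", "Bacteroidetes",
  "Cyanobacteria", "Firmicutes", "Spirochaetes", "Chloroflexi",
  "Planctomycetes", "Verrucomicrobia", "Acidobacteria",
  "Deinococcus-Thermus", "Fusobacteria", "Chlamydiae", "Thermotogae",
  "Chlorobi"
)

## Approximate domain lengths (aa) used to lay out hit coordinates.
DOMAIN_LENGTHS <- c(
  MCE = 81, DUF3407 = 180, "ABC_tran" = 137, "AAA_21" = 120, MlaE = 240,
  PqiA = 170, DUF330 = 150, MlaC = 190, STAS = 110, Tol = 130
)

#' Default planted gene-neighbourhood templates
#'
#' Slot-indexed canonical architecture strings emulating the canonical
#' operon contexts: type I MCE genes sit downstream of an ABC-transporter
#' ATPase and permease with a DUF330 lipoprotein gene downstream
#' (mlaFEDCB-style); type III genes have a twin-PqiA-domain gene upstream
#' and DUF330 downstream (pqiA-pqiB-ymbA); type IV genes have the twin-PqiA
#' gene upstream and no DUF330 (yebS-yebT).
#'
#' @return Named list (types I/III/IV) of named character vectors
#'   (slot -> architecture string).
#' @export
default_context_templates <- function() {
  list(
    I   = c("-2" = "ABC_tran", "-1" = "MlaE", "+1" = "DUF330"),
    III = c("-1" = "PqiA, PqiA", "+1" = "DUF330"),
    IV  = c("-1" = "PqiA, PqiA")
  )
}

default_type_profile <- function(n_phyla) {
  phyla <- if (n_phyla <= length(BACTERIAL_PHYLA)) {
    BACTERIAL_PHYLA[seq_len(n_phyla)]
  } else {
    c(BACTERIAL_PHYLA,
      sprintf("Phylum_%02d", seq_len(n_phyla - length(BACTERIAL_PHYLA))))
  }
  prof <- matrix(0, nrow = n_phyla, ncol = 4,
                 dimnames = list(phyla, c("I", "II", "III", "IV")))
  prof[, "I"] <- 0.9
  prof[1L, "I"] <- 0.4                      # an early-branching low-MCE phylum
  if ("Actinobacteria" %in% phyla) prof["Actinobacteria", "II"] <- 0.9
  if ("Proteobacteria" %in% phyla) {
    prof["Proteobacteria", c("III", "IV")] <- c(0.8, 0.5)
  }
  prof
}

#' Configuration for the synthetic-dataset generator
#'
#' Defaults state the world the analysis assumes: type I widespread across
#' phyla, type II confined to Actinobacteria, types III/IV confined to
#' Proteobacteria (IV rarer); operon contexts per
#' [default_context_templates()]; planted protein families separated across
#' the 1e-15 e-value boundary; sub-threshold decoy hits as noise.
#'
#' @param seed Integer master seed; the whole bundle is deterministic in it.
#' @param n_phyla,species_per_phylum,genomes_per_species Taxonomy shape.
#' @param type_profile Phylum x type matrix of planting probabilities
#'   (rownames = phyla); default [default_type_profile()]. Presence is
#'   planted at species level: every genome of a species carries the same
#'   types, so representative choice cannot change prevalence.
#' @param decoy_hit_rate Mean sub-threshold noise hits per protein (Poisson).
#' @param overlap_conflict_rate Fraction of filler proteins given a planted
#'   same-clan overlapping hit pair (intended survivor = higher bit score,
#'   recorded in the ground truth).
#' @param filler_genes_per_genome Number of non-MCE filler genes per genome.
#' @param none_arch_prob Probability a filler gene has no significant domain
#'   (architecture `"NONE"`), emulating the large fraction of
#'   Pfam-unannotated bacterial genes.
#' @param atpase_synonym_prob Probability the planted ATPase context gene
#'   carries the double annotation `ABC_tran, AAA_21` (canonicalised to
#'   `ABC_tran` by the default synonym map).
#' @param far_gene_fraction Fraction of filler runs placed beyond the 10 kb
#'   window to exercise the window cut.
#' @param intergenic_range Uniform intergenic spacing range in bp.
#' @param within_family_evalue_ceiling,between_family_evalue_floor Planted
#'   family separation: within-family alignment e-values are drawn
#'   log-uniformly at or below the ceiling (default 1e-15), between-family
#'   strictly above the floor (default 1e-12); ceiling must be < floor.
#' @param between_family_edge_rate Fraction of cross-family pairs emitted.
#' @param eukaryote_species Number of extra eukaryote species planted with a
#'   type I protein (for the contamination screen).
#' @param default_threshold Gathering bit-score floor; planted hits score
#'   above it, decoys strictly below.
#' @param window_bp Neighbourhood window used to size isolation gaps.
#' @param context_templates Planted neighbourhood templates, as
#'   [default_context_templates()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_phyla = 8L,
                              species_per_phylum = 10L,
                              genomes_per_species = 1L,
                              type_profile = NULL,
                              decoy_hit_rate = 0.5,
                              overlap_conflict_rate = 0.05,
                              filler_genes_per_genome = 24L,
                              none_arch_prob = 0.5,
                              atpase_synonym_prob = 0.3,
                              far_gene_fraction = 0.1,
                              intergenic_range = c(50L, 500L),
                              within_family_evalue_ceiling = 1e-15,
                              between_family_evalue_floor = 1e-12,
                              between_family_edge_rate = 0.05,
                              eukaryote_species = 1L,
                              default_threshold = 25,
                              window_bp = 10000L,
                              context_templates = default_context_templates()) {
  cfg <- as.list(environment())
  if (is.null(cfg$type_profile)) {
    cfg$type_profile <- default_type_profile(n_phyla)
  }
  if (!is.matrix(cfg$type_profile) ||
      nrow(cfg$type_profile) != n_phyla ||
      !all(colnames(cfg$type_profile) == c("I", "II", "III", "IV"))) {
    config_error("type_profile must be an n_phyla x 4 matrix with columns ",
                 "I, II, III, IV")
  }
  if (any(cfg$type_profile < 0 | cfg$type_profile > 1)) {
    config_error("type_profile probabilities must lie in [0, 1]")
  }
  if (within_family_evalue_ceiling >= between_family_evalue_floor) {
    config_error("within_family_evalue_ceiling (",
                 within_family_evalue_ceiling,
                 ") must be smaller than between_family_evalue_floor (",
                 between_family_evalue_floor, ")")
  }
  for (p in c("decoy_hit_rate", "overlap_conflict_rate", "none_arch_prob",
              "atpase_synonym_prob", "far_gene_fraction",
              "between_family_edge_rate")) {
    if (cfg[[p]] < 0 || (p != "decoy_hit_rate" && cfg[[p]] > 1)) {
      config_error(p, " out of range")
    }
  }
  structure(cfg, class = "simulation_config")
}

## aa length of a protein drawn for an architecture, with domain layout.
## Returns list(length, hits = data.table(domain_name, clan_id, start, end)).
plant_domain_layout <- function(domains) {
  if (length(domains) == 0L) {
    return(list(length = sample(100:400, 1L),
                hits = data.table(domain_name = character(),
                                  clan_id = character(),
                                  start = integer(), end = integer())))
  }
  dlen <- DOMAIN_LENGTHS[domains]
  dlen[is.na(dlen)] <- sample(80:150, sum(is.na(dlen)), replace = TRUE)
  pos <- sample(15:40, 1L)
  starts <- integer(length(domains))
  ends <- integer(length(domains))
  for (i in seq_along(domains)) {
    starts[i] <- pos
    ends[i] <- pos + as.integer(dlen[i]) - 1L
    pos <- ends[i] + sample(5:30, 1L)
  }
  list(length = ends[length(ends)] + sample(10L:60L, 1L),
       hits = data.table(domain_name = domains, clan_id = NA_character_,
                         start = starts, end = ends))
}

type_arch <- function(type) {
  switch(type,
         I = "MCE",
         II = c("MCE", "DUF3407"),
         III = rep("MCE", 3L),
         IV = rep("MCE", 7L))
}

## Gene block (genomic order, + orientation) for a planted focal type.
## Each element: list(role, arch = character vector of domains).
context_block <- function(type, template, atpase_synonym_prob) {
  slot_names <- names(template)
  up <- template[startsWith(slot_names, "-")]
  down <- template[startsWith(slot_names, "+")]
  up <- up[order(-as.integer(sub("-", "", names(up))))]   # -k .. -1
  down <- down[order(as.integer(sub("\\+", "", names(down))))]
  to_spec <- function(arch_str) {
    doms <- strsplit(arch_str, ", ", fixed = TRUE)[[1L]]
    if (identical(doms, "ABC_tran") && runif(1) < atpase_synonym_prob) {
      doms <- c("ABC_tran", "AAA_21")
    }
    list(role = "context", arch = doms)
  }
  c(lapply(unname(up), to_spec),
    list(list(role = "focal", arch = type_arch(type), type = type)),
    lapply(unname(down), to_spec))
}

filler_spec <- function(cfg) {
  if (runif(1) < cfg$none_arch_prob) {
    list(role = "filler", arch = character())
  } else {
    list(role = "filler",
         arch = sprintf("NBR%03d", sample.int(30L, sample(1:2, 1L))))
  }
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Emits (and optionally writes) the four pipeline inputs — domain hit table,
#' protein metadata, GFF3 gene table, all-vs-all alignment table — together
#' with the planted truth: per-protein architecture and type, per-species
#' type presence, per-protein family id, and per-focal-gene context class.
#' Planted hits score above the gathering threshold, decoys strictly below;
#' within-family alignment e-values sit at or below the family ceiling and
#' cross-family e-values strictly above the floor; operon contexts follow
#' `config$context_templates` with randomised intergenic spacing. Everything
#' is deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created); NULL to skip writing files.
#' @return Invisibly, a list: `hits`, `proteins`, `loci`, `alignments`
#'   (in-memory tables), `ground_truth` (list of `architectures`,
#'   `presence`, `families`, `contexts`), `config`, and `paths` when `dir`
#'   was given.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  out <- with_seed(config$seed, simulate_dataset_impl(config))
  if (!is.null(dir)) {
    out$paths <- write_bundle(out, dir)
    out$dir <- dir
  }
  invisible(out)
}

simulate_dataset_impl <- function(cfg) {
  phyla <- rownames(cfg$type_profile)
  types <- c("I", "II", "III", "IV")

  ## ---- taxonomy and species-level type presence -------------------------
  species <- CJ(phylum_idx = seq_along(phyla),
                idx = seq_len(cfg$species_per_phylum), sorted = FALSE)
  species[, phylum := phyla[phylum_idx]]
  species[, species_id := sprintf("sp_%02d_%02d", phylum_idx, idx)]
  species[, phylum_idx := NULL]
  species[, superkingdom := "Bacteria"]
  if (cfg$eukaryote_species > 0L) {
    species <- rbind(species, data.table(
      phylum = "Streptophyta", idx = seq_len(cfg$eukaryote_species),
      species_id = sprintf("sp_Strept_%02d", seq_len(cfg$eukaryote_species)),
      superkingdom = "Eukaryota"))
  }
  presence <- species[, {
    p <- if (phylum %in% phyla) cfg$type_profile[phylum, ] else
      c(I = 1, II = 0, III = 0, IV = 0)   # planted eukaryote type I
    setNames(as.list(runif(4) < p), types)
  }, by = .(species_id, phylum, superkingdom)]

  ## ---- per-genome gene layouts ------------------------------------------
  genomes <- species[, .(genome_id = sprintf("%s_g%d", species_id,
                                             seq_len(cfg$genomes_per_species))),
                     by = .(species_id, phylum, superkingdom)]

  gene_rows <- list()
  hit_rows <- list()
  prot_rows <- list()
  truth_arch <- list()
  truth_ctx <- list()
  gap_of <- function() sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], 1L)

  for (gi in seq_len(nrow(genomes))) {
    g <- genomes[gi]
    pres <- presence[species_id == g$species_id]
    planted_types <- types[unlist(pres[, ..types])]
    ## gene specs in genomic order: filler runs interleaved with context
    ## blocks, each block isolated by a > window gap on both sides
    specs <- list()
    gaps <- integer()           # gap BEFORE each gene
    big_gap <- function() cfg$window_bp + sample(2000:5000, 1L)
    n_runs <- length(planted_types) + 1L
    run_sizes <- diff(round(seq(0, cfg$filler_genes_per_genome,
                                length.out = n_runs + 1L)))
    add <- function(spec, gap) {
      specs[[length(specs) + 1L]] <<- spec
      gaps[length(gaps) + 1L] <<- gap
    }
    for (run in seq_len(n_runs)) {
      for (k in seq_len(run_sizes[run])) {
        far <- runif(1) < cfg$far_gene_fraction
        add(filler_spec(cfg), if (far) big_gap() else gap_of())
      }
      if (run <= length(planted_types)) {
        ty <- planted_types[run]
        tmpl <- cfg$context_templates[[ty]]
        block <- if (is.null(tmpl)) {
          list(list(role = "focal", arch = type_arch(ty), type = ty))
        } else {
          context_block(ty, tmpl, cfg$atpase_synonym_prob)
        }
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") block <- rev(block)
        for (bi in seq_along(block)) {
          block[[bi]]$strand <- strand
          add(block[[bi]], if (bi == 1L) big_gap() else gap_of())
        }
        ## the gap after the block is widened in the layout pass below
      }
    }
    ## lay out coordinates
    contig <- sprintf("ctg_%s", g$genome_id)
    pos <- 1000L
    n <- length(specs)
    for (si in seq_len(n)) {
      sp <- specs[[si]]
      ## big gap after a block: if previous spec was part of a block and this
      ## one is a filler, widen the gap
      if (si > 1L && specs[[si - 1L]]$role %in% c("focal", "context") &&
          sp$role == "filler") {
        gaps[si] <- big_gap()
      }
      layout <- plant_domain_layout(sp$arch)
      gene_len <- 3L * layout$length
      start <- pos + gaps[si]
      end <- start + gene_len - 1L
      pos <- end
      gene_id <- sprintf("%s_gene%04d", g$genome_id, si)
      protein_id <- sprintf("%s_p%04d", g$genome_id, si)
      strand <- sp$strand %||% sample(c("+", "-"), 1L)
      gene_rows[[length(gene_rows) + 1L]] <- data.table(
        gene_id = gene_id, genome_id = g$genome_id, contig = contig,
        start = start, end = end, strand = strand, protein_id = protein_id)

      hits <- layout$hits
      planted <- hits$domain_name
      hits[, `:=`(protein_id = protein_id,
                  bit_score = runif(.N, 30, 100),
                  e_value = 10^-runif(.N, 8, 30))]
      ## planted same-clan overlap conflict on some fillers
      if (sp$role == "filler" && runif(1) < cfg$overlap_conflict_rate) {
        cstart <- layout$length + 20L
        bits <- sort(runif(2, 30, 60))
        conf <- data.table(
          domain_name = c("CONF_A", "CONF_B"), clan_id = "CL_CONF",
          start = c(cstart, cstart + 40L),
          end = c(cstart + 90L, cstart + 130L),
          protein_id = protein_id, bit_score = bits,
          e_value = 10^-runif(2, 8, 20))
        survivor <- conf$domain_name[which.max(conf$bit_score)]
        planted <- c(planted, survivor)   # conflict lies 3' of other domains
        hits <- rbind(hits, conf)
        layout$length <- cstart + 130L + 20L
      }
      ## sub-threshold decoy noise
      n_decoy <- rpois(1L, cfg$decoy_hit_rate)
      if (n_decoy > 0L) {
        dstart <- sample.int(max(layout$length - 40L, 1L), n_decoy,
                             replace = TRUE)
        hits <- rbind(hits, data.table(
          domain_name = sprintf("DCY%03d", sample.int(30L, n_decoy,
                                                      replace = TRUE)),
          clan_id = NA_character_,
          start = dstart, end = dstart + sample(20:60, n_decoy,
                                                replace = TRUE),
          protein_id = protein_id,
          bit_score = runif(n_decoy, 5, cfg$default_threshold - 0.1),
          e_value = 10^-runif(n_decoy, 0, 3)))
      }
      if (nrow(hits)) hit_rows[[length(hit_rows) + 1L]] <- hits

      prot_rows[[length(prot_rows) + 1L]] <- data.table(
        protein_id = protein_id, genome_id = g$genome_id,
        species_id = g$species_id, phylum = g$phylum,
        superkingdom = g$superkingdom, length = layout$length)

      canonical <- merge_synonyms(arch_string(planted))
      truth_arch[[length(truth_arch) + 1L]] <- data.table(
        protein_id = protein_id,
        type_label = classify_type(planted),
        mce_count = sum(planted == "MCE"),
        domains = canonical)
      if (sp$role == "focal") {
        truth_ctx[[length(truth_ctx) + 1L]] <- data.table(
          gene_id = gene_id, protein_id = protein_id, genome_id = g$genome_id,
          species_id = g$species_id, phylum = g$phylum,
          context_class = sp$type, strand = strand)
      }
    }
  }

  loci <- rbindlist(gene_rows)
  setorder(loci, genome_id, contig, start)
  hits <- rbindlist(hit_rows, use.names = TRUE)
  setcolorder(hits, c("protein_id", "domain_name", "clan_id", "start", "end",
                      "bit_score", "e_value"))
  hits[, is_mce := domain_name == "MCE"]
  setorder(hits, protein_id, start, domain_name)
  proteins <- rbindlist(prot_rows)
  arch_truth <- rbindlist(truth_arch)
  setorder(arch_truth, protein_id)
  contexts <- rbindlist(truth_ctx)

  ## ---- planted families and all-vs-all alignments -----------------------
  mce <- arch_truth[mce_count > 0L][proteins, on = "protein_id",
                                    nomatch = NULL]
  mce[, family_id := paste0("fam_", phylum, "_", type_label)]
  families <- mce[, .(protein_id, family_id)]
  aln <- simulate_alignments(mce, cfg)

  list(hits = hits, proteins = proteins, loci = loci, alignments = aln,
       ground_truth = list(architectures = arch_truth,
                           presence = presence[, c("species_id", "phylum",
                                                   "superkingdom", types),
                                               with = FALSE],
                           families = families, contexts = contexts),
       config = cfg)
}

simulate_alignments <- function(mce, cfg) {
  ids <- mce$protein_id
  fam <- setNames(mce$family_id, ids)
  len <- setNames(mce$length, ids)
  rows <- list()
  push <- function(q, s, pct, ev) {
    al <- as.integer(round(min(len[q], len[s]) * runif(1, 0.6, 1)))
    rows[[length(rows) + 1L]] <<- data.table(
      query_id = q, subject_id = s, pct_identity = round(pct, 1),
      aln_length = al,
      mismatches = as.integer(round(al * (1 - pct / 100))),
      gap_opens = sample(0:5, 1L), q_start = 1L, q_end = al,
      s_start = 1L, s_end = al,
      e_value = signif(ev, 3),
      bit_score = round(30 + 2 * pmin(-log10(ev + 1e-300), 200), 1))
  }
  ## self hits (exercise drop_self)
  for (q in ids) push(q, q, 100, 1e-180)
  by_fam <- split(ids, fam[ids])
  for (members in by_fam) {
    if (length(members) < 2L) next
    prs <- utils::combn(members, 2L)
    for (k in seq_len(ncol(prs))) {
      ev <- 10^-runif(1, -log10(cfg$within_family_evalue_ceiling), 30)
      pct <- runif(1, 55, 95)
      push(prs[1L, k], prs[2L, k], pct, ev)
      if (runif(1) < 0.2) {      # occasional reciprocal line
        push(prs[2L, k], prs[1L, k], pct, ev * 10^runif(1, -1, 1))
      }
    }
  }
  ## sampled cross-family pairs, strictly above the floor
  fams <- names(by_fam)
  if (length(fams) >= 2L) {
    fam_prs <- utils::combn(fams, 2L)
    for (k in seq_len(ncol(fam_prs))) {
      a <- by_fam[[fam_prs[1L, k]]]
      b <- by_fam[[fam_prs[2L, k]]]
      n_pairs <- max(1L, round(cfg$between_family_edge_rate *
                                 length(a) * length(b)))
      for (dummy in seq_len(n_pairs)) {
        ev <- 10^-runif(1, 3, -log10(cfg$between_family_evalue_floor) - 0.05)
        push(sample(a, 1L), sample(b, 1L), runif(1, 10, 35), ev)
      }
    }
  }
  aln <- rbindlist(rows)
  setorder(aln, query_id, subject_id, e_value)
  aln[]
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  paths <- list(
    hits = file.path(dir, "hits.domtbl"),
    proteins = file.path(dir, "proteins.tsv"),
    genes = file.path(dir, "genes.gff3"),
    alignments = file.path(dir, "alignments.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_domain_hits(bundle$hits, paths$hits)
  write_proteins(bundle$proteins, paths$proteins)
  write_gff(bundle$loci, paths$genes)
  write_alignments(bundle$alignments, paths$alignments)
  gt <- bundle$ground_truth
  fwrite(gt$architectures, file.path(gt_dir, "architectures.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(gt$presence, file.path(gt_dir, "presence.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(gt$families, file.path(gt_dir, "families.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(gt$contexts, file.path(gt_dir, "contexts.tsv"),
         sep = "\t", quote = FALSE)
  cfg <- bundle$config
  cfg$type_profile <- as.data.frame(cfg$type_profile)
  cfg$context_templates <- lapply(cfg$context_templates, as.list)
  manifest <- list(
    tool = "mcetools",
    version = as.character(utils::packageVersion("mcetools")),
    seed = bundle$config$seed,
    config = unclass(cfg),
    counts = list(proteins = nrow(bundle$proteins),
                  genes = nrow(bundle$loci),
                  domain_hits = nrow(bundle$hits),
                  alignments = nrow(bundle$alignments))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}

#' Miniature hand-written E. coli-style fixture
#'
#' A deterministic three-operon toy genome mirroring the canonical MCE
#' operons of \emph{E. coli} K-12: \code{mlaFEDCB} (MlaD, one MCE domain;
#' ATPase and permease genes upstream, MlaC/STAS genes downstream),
#' \code{pqiA-pqiB-ymbA} (PqiB, three MCE domains; twin-PqiA-domain gene
#' upstream, DUF330 gene downstream) and \code{yebS-yebT} on the minus
#' strand (YebT, seven MCE domains; twin-PqiA-domain gene upstream, no
#' DUF330). Used as the documentation worked example.
#'
#' @param dir Optional directory to write the bundle files into.
#' @return Same bundle structure as [simulate_dataset()] (without planted
#'   families beyond the three MCE proteins).
#' @export
ecoli_fixture <- function(dir = NULL) {
  gnm <- "ECOLI_K12"; sp <- "Escherichia_coli"; ctg <- "NC_000913_mini"
  gene <- function(id, start, end, strand, pid) {
    data.table(gene_id = id, genome_id = gnm, contig = ctg, start = start,
               end = end, strand = strand, protein_id = pid)
  }
  loci <- rbind(
    gene("mlaF", 1000L, 1812L, "+", "P_MLAF"),
    gene("mlaE", 1833L, 2612L, "+", "P_MLAE"),
    gene("mlaD", 2633L, 3193L, "+", "P_MLAD"),
    gene("mlaC", 3214L, 3846L, "+", "P_MLAC"),
    gene("mlaB", 3867L, 4157L, "+", "P_MLAB"),
    gene("pqiA", 20000L, 21283L, "+", "P_PQIA"),
    gene("pqiB", 21304L, 22947L, "+", "P_PQIB"),
    gene("ymbA", 22968L, 23533L, "+", "P_YMBA"),
    gene("yebT", 40000L, 42636L, "-", "P_YEBT"),
    gene("yebS", 42703L, 44004L, "-", "P_YEBS")
  )
  hit <- function(pid, dom, start, end, bit, ev) {
    data.table(protein_id = pid, domain_name = dom, clan_id = NA_character_,
               start = start, end = end, bit_score = bit, e_value = ev)
  }
  mce_tandem <- function(pid, n, first = 35L) {
    rbindlist(lapply(seq_len(n), function(k) {
      s <- first + (k - 1L) * 110L
      hit(pid, "MCE", s, s + 80L, 70 + k, 10^-(18 + k))
    }))
  }
  hits <- rbind(
    hit("P_MLAF", "ABC_tran", 30L, 166L, 88.1, 1e-26),
    hit("P_MLAE", "MlaE", 12L, 251L, 95.4, 1e-30),
    mce_tandem("P_MLAD", 1L),
    hit("P_MLAC", "MlaC", 25L, 205L, 77.0, 1e-22),
    hit("P_MLAB", "STAS", 8L, 92L, 54.2, 1e-14),
    hit("P_PQIA", "PqiA", 20L, 189L, 81.3, 1e-24),
    hit("P_PQIA", "PqiA", 230L, 399L, 79.9, 1e-23),
    mce_tandem("P_PQIB", 3L),
    hit("P_YMBA", "DUF330", 22L, 171L, 63.5, 1e-18),
    mce_tandem("P_YEBT", 7L),
    hit("P_YEBS", "PqiA", 18L, 187L, 83.0, 1e-25),
    hit("P_YEBS", "PqiA", 240L, 409L, 80.5, 1e-24)
  )
  hits[, is_mce := domain_name == "MCE"]
  proteins <- data.table(
    protein_id = c("P_MLAF", "P_MLAE", "P_MLAD", "P_MLAC", "P_MLAB",
                   "P_PQIA", "P_PQIB", "P_YMBA", "P_YEBT", "P_YEBS"),
    genome_id = gnm, species_id = sp, phylum = "Proteobacteria",
    superkingdom = "Bacteria",
    length = c(271L, 260L, 187L, 211L, 97L, 428L, 548L, 188L, 879L, 434L))
  ## the three MCE proteins are mutually remote: below-threshold e-values
  aln <- rbindlist(list(
    data.table(query_id = "P_MLAD", subject_id = "P_PQIB",
               pct_identity = 22.5, e_value = 1e-6, bit_score = 38.1),
    data.table(query_id = "P_MLAD", subject_id = "P_YEBT",
               pct_identity = 21.0, e_value = 3e-5, bit_score = 35.0),
    data.table(query_id = "P_PQIB", subject_id = "P_YEBT",
               pct_identity = 27.9, e_value = 2e-8, bit_score = 44.6)
  ))
  aln[, `:=`(aln_length = 150L, mismatches = 110L, gap_opens = 2L,
             q_start = 1L, q_end = 150L, s_start = 1L, s_end = 150L)]
  setcolorder(aln, c("query_id", "subject_id", "pct_identity", "aln_length",
                     "mismatches", "gap_opens", "q_start", "q_end",
                     "s_start", "s_end", "e_value", "bit_score"))
  bundle <- list(
    hits = hits, proteins = proteins, loci = loci, alignments = aln,
    ground_truth = list(
      architectures = data.table(
        protein_id = c("P_MLAD", "P_PQIB", "P_YEBT"),
        type_label = c("I", "III", "IV"),
        mce_count = c(1L, 3L, 7L),
        domains = c("MCE", arch_string(rep("MCE", 3)),
                    arch_string(rep("MCE", 7)))),
      presence = data.table(species_id = sp, phylum = "Proteobacteria",
                            superkingdom = "Bacteria",
                            I = TRUE, II = FALSE, III = TRUE, IV = TRUE),
      families = data.table(protein_id = character(),
                            family_id = character()),
      contexts = data.table(
        gene_id = c("mlaD", "pqiB", "yebT"),
        protein_id = c("P_MLAD", "P_PQIB", "P_YEBT"),
        genome_id = gnm, species_id = sp, phylum = "Proteobacteria",
        context_class = c("I", "III", "IV"),
        strand = c("+", "+", "-"))),
    config = NULL
  )
  if (!is.null(dir)) {
    bundle$paths <- write_bundle_min(bundle, dir)
    bundle$dir <- dir
  }
  invisible(bundle)
}

write_bundle_min <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    hits = file.path(dir, "hits.domtbl"),
    proteins = file.path(dir, "proteins.tsv"),
    genes = file.path(dir, "genes.gff3"),
    alignments = file.path(dir, "alignments.tsv")
  )
  write_domain_hits(bundle$hits, paths$hits)
  write_proteins(bundle$proteins, paths$proteins)
  write_gff(bundle$loci, paths$genes)
  write_alignments(bundle$alignments, paths$alignments)
  paths
}
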