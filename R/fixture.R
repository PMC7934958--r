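## Synthetic transcript-evidence fixtures with planted ground truth.
## Each species gets a full evidence bundle (FASTA, domtblout, homology
## table, annotation, counts, taxonomy) containing true multi-isoform
## genes, paralogs, and one decoy per filter the cascade claims to handle;
## a truth table records every transcript's intended fate. Residues are
## poly-alanine with length control: only lengths, headers and hit tables
## carry signal.

#' Planting plan for a transcriptome fixture
#'
#' @param n_true_genes clean true immune genes per species (cycled over
#'   the non-AMP families of the definition table).
#' @param max_isoforms isoforms per true gene are drawn from
#'   `1:max_isoforms`.
#' @param n_paralog_pairs pairs of genes sharing an assembly component but
#'   differing in gene index (both are real genes and must both count).
#' @param decoys named integer vector: how many of each decoy type to
#'   plant. Types: `fragment` (99 aa non-AMP), `amp_short` (45 aa
#'   defensin, must survive), `family_disagreement`, `annotation_mismatch`,
#'   `low_expression` (true gene, < 5 counts), `contaminant`
#'   (non-metazoan), `no_domain`, `weak_domain` (i-E-value above
#'   threshold), `no_homology`.
#' @return list of class `fixture_plant`.
#' @export
fixture_plant <- function(n_true_genes = 8, max_isoforms = 3,
                          n_paralog_pairs = 1,
                          decoys = c(
                            fragment = 1, amp_short = 1,
                            family_disagreement = 1,
                            annotation_mismatch = 1, low_expression = 1,
                            contaminant = 1, no_domain = 1,
                            weak_domain = 1, no_homology = 1
                          )) {
  known <- c(
    "fragment", "amp_short", "family_disagreement", "annotation_mismatch",
    "low_expression", "contaminant", "no_domain", "weak_domain",
    "no_homology"
  )
  bad <- setdiff(names(decoys), known)
  if (length(bad) > 0) stop("unknown decoy type(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      n_true_genes = n_true_genes, max_isoforms = max_isoforms,
      n_paralog_pairs = n_paralog_pairs,
      decoys = decoys[decoys > 0]
    ),
    class = "fixture_plant"
  )
}

host_lineage <- "Metazoa; Arthropoda; Insecta; Blattodea"
contaminant_lineages <- c(
  "Bacteria; Proteobacteria", "Fungi; Ascomycota", "Viridiplantae; Streptophyta"
)

#' Generate a transcriptome evidence fixture with planted truth
#'
#' Writes, per species, a complete evidence bundle under
#' `dir/<species>/`, plus `families.tsv`, `tree.nwk` (when species are
#' fixture-tree tips) and `truth.json` at the top level. With a fixed
#' seed the output is byte-identical across runs.
#'
#' @param dir output directory (created).
#' @param species character vector of species names (default: three
#'   fixture-tree tips spanning solitary, subsocial and social lineages).
#' @param defs family definitions.
#' @param plant a [fixture_plant()].
#' @param seed integer seed.
#' @return invisibly, a list with `dir`, `truth` (data.frame: species,
#'   transcript_id, fate, stage, family, gene) and `expected_matrix`
#'   (families x species counts the cascade must reproduce).
#' @export
generate_transcriptome_fixture <- function(dir,
                                           species = c(
                                             "Blattella_germanica",
                                             "Cryptocercus_punctulatus",
                                             "Macrotermes_natalensis"
                                           ),
                                           defs = default_family_definitions(),
                                           plant = fixture_plant(),
                                           seed = 1) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_family_definitions(defs, file.path(dir, "families.tsv"))
  ft <- fixture_tree()
  if (all(species %in% ft$phy$tip.label)) {
    write_species_tree(
      species_tree(ape::keep.tip(ft$phy, species), ultrametric = FALSE),
      file.path(dir, "tree.nwk")
    )
  }
  truth_all <- list()
  for (sp in species) {
    sp_dir <- file.path(dir, sp)
    dir.create(sp_dir, showWarnings = FALSE)
    truth_all[[sp]] <- write_species_fixture(sp_dir, sp, defs, plant)
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    dataframe = "rows", pretty = TRUE
  )
  kept <- truth[truth$fate %in% c("accepted", "flagged"), , drop = FALSE]
  expected <- table(
    factor(kept$family, levels = defs$family),
    factor(kept$species, levels = species)
  )
  em <- matrix(as.integer(expected), nrow(defs), length(species),
    dimnames = list(defs$family, species)
  )
  invisible(list(dir = dir, truth = truth, expected_matrix = em))
}

# one species' bundle; returns the truth rows
write_species_fixture <- function(sp_dir, sp, defs, plant) {
  rec <- new.env(parent = emptyenv())
  rec$fasta_id <- character(0)
  rec$fasta_len <- integer(0)
  rec$dom <- list()
  rec$hom <- list()
  rec$ann <- list()
  rec$cnt <- list()
  rec$tax <- list()
  rec$truth <- list()
  rec$dn <- 100L

  fam_domain <- vapply(
    strsplit(defs$domains, ";", fixed = TRUE), `[[`, character(1), 1
  )
  names(fam_domain) <- defs$family
  generic_fams <- defs$family[!defs$is_amp]

  add_tx <- function(id, len, counts, taxon = host_lineage) {
    rec$fasta_id <- c(rec$fasta_id, id)
    rec$fasta_len <- c(rec$fasta_len, len)
    rec$cnt[[id]] <- counts
    rec$tax[[id]] <- taxon
  }
  add_dom <- function(id, domain, ievalue, score) {
    rec$dom[[length(rec$dom) + 1L]] <- data.frame(
      protein = id, domain = domain, i_evalue = ievalue, score = score,
      env_from = 5L, env_to = 90L, stringsAsFactors = FALSE
    )
  }
  add_hom <- function(id, family, bitscore, evalue, ref = 1L) {
    rec$hom[[length(rec$hom) + 1L]] <- data.frame(
      qseqid = id, sseqid = sprintf("%s|REF%03d", family, ref),
      pident = 65.0, length = 120L, mismatch = 40L, gapopen = 2L,
      qstart = 1L, qend = 120L, sstart = 1L, send = 120L,
      evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE
    )
  }
  add_truth <- function(id, fate, stage, family, gene) {
    rec$truth[[length(rec$truth) + 1L]] <- data.frame(
      species = sp, transcript_id = id, fate = fate, stage = stage,
      family = family, gene = gene, stringsAsFactors = FALSE
    )
  }
  new_component <- function() {
    rec$dn <- rec$dn + 1L
    sprintf("DN%d_c0", rec$dn)
  }
  tx_id <- function(component, g, i) {
    sprintf("TRINITY_%s_g%d_i%d", component, g, i)
  }

  # a clean true gene: isoforms with distinct lengths, the longest is the
  # expected representative
  plant_true_gene <- function(family, component, g, n_iso,
                              low_expression = FALSE, short_amp = FALSE) {
    lens <- if (short_amp) {
      sort(sample(40:55, n_iso)) # AMPs are short by nature
    } else {
      sort(sample(seq(120L, 400L, by = 7L), n_iso))
    }
    total <- if (low_expression) 4 else sample(20:300, 1)
    per_iso <- diff(c(0, sort(stats::runif(n_iso - 1)), 1)) * total
    per_iso <- round(per_iso, 1)
    gene <- paste(component, sprintf("g%d", g), sep = "_")
    for (i in seq_len(n_iso)) {
      id <- tx_id(component, g, i)
      add_tx(id, lens[i], per_iso[i])
      add_dom(id, fam_domain[[family]], 10^-sample(10:40, 1), 80 + i)
      add_hom(id, family, 150 + sample(10:90, 1), 1e-40)
      rec$ann[[id]] <- family
      is_rep <- lens[i] == max(lens)
      if (is_rep) {
        add_truth(
          id, if (low_expression) "flagged" else "accepted",
          if (low_expression) "low-expression" else "accepted",
          family, gene
        )
      } else {
        add_truth(id, "dropped", "isoform-collapse", family, gene)
      }
    }
  }

  fam_cycle <- rep_len(generic_fams, plant$n_true_genes)
  for (gidx in seq_len(plant$n_true_genes)) {
    plant_true_gene(
      fam_cycle[gidx], new_component(), 1L,
      sample(seq_len(plant$max_isoforms), 1)
    )
  }
  for (p in seq_len(plant$n_paralog_pairs)) {
    comp <- new_component()
    fam <- sample(generic_fams, 1)
    plant_true_gene(fam, comp, 1L, 1L)
    plant_true_gene(fam, comp, 2L, 1L)
  }

  dec <- plant$decoys
  n_of <- function(type) if (type %in% names(dec)) dec[[type]] else 0L
  for (i in seq_len(n_of("amp_short"))) {
    plant_true_gene("defensin", new_component(), 1L, 1L, short_amp = TRUE)
  }
  for (i in seq_len(n_of("low_expression"))) {
    plant_true_gene(sample(generic_fams, 1), new_component(), 1L, 1L,
      low_expression = TRUE
    )
  }
  for (i in seq_len(n_of("fragment"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 99L, sample(20:100, 1))
    add_dom(id, fam_domain[["CTL"]], 1e-20, 90)
    add_hom(id, "CTL", 180, 1e-30)
    rec$ann[[id]] <- "CTL"
    add_truth(id, "dropped", "length", "CTL", NA_character_)
  }
  for (i in seq_len(n_of("family_disagreement"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 200L, sample(20:100, 1))
    add_dom(id, fam_domain[["CTL"]], 1e-25, 95)
    add_hom(id, "GNBP", 250, 1e-60) # best hit disagrees
    add_hom(id, "CTL", 190, 1e-45, ref = 2L)
    rec$ann[[id]] <- "CTL"
    add_truth(id, "dropped", "family-disagreement", "CTL", NA_character_)
  }
  for (i in seq_len(n_of("annotation_mismatch"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 220L, sample(20:100, 1))
    add_dom(id, fam_domain[["CTL"]], 1e-22, 92)
    add_hom(id, "CTL", 200, 1e-50)
    rec$ann[[id]] <- "CLIP"
    add_truth(id, "dropped", "annotation-mismatch", "CTL", NA_character_)
  }
  for (i in seq_len(n_of("contaminant"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 180L, sample(20:100, 1),
      taxon = contaminant_lineages[1 + (i - 1) %% length(contaminant_lineages)]
    )
    add_dom(id, fam_domain[["lysozyme"]], 1e-15, 70)
    add_hom(id, "lysozyme", 150, 1e-35)
    rec$ann[[id]] <- "lysozyme"
    add_truth(id, "dropped", "taxonomy", NA_character_, NA_character_)
  }
  for (i in seq_len(n_of("no_domain"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 300L, sample(20:100, 1))
    add_truth(id, "dropped", "no-domain", NA_character_, NA_character_)
  }
  for (i in seq_len(n_of("weak_domain"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 250L, sample(20:100, 1))
    add_dom(id, fam_domain[["GNBP"]], 1e-3, 15) # above the E-value bar
    add_truth(id, "dropped", "no-domain", NA_character_, NA_character_)
  }
  for (i in seq_len(n_of("no_homology"))) {
    id <- tx_id(new_component(), 1L, 1L)
    add_tx(id, 210L, sample(20:100, 1))
    add_dom(id, fam_domain[["PGRP"]], 1e-18, 85)
    rec$ann[[id]] <- "PGRP"
    add_truth(id, "dropped", "no-homology", "PGRP", NA_character_)
  }

  o <- order(rec$fasta_id)
  write_protein_fasta(
    rec$fasta_id[o],
    vapply(rec$fasta_len[o], function(n) strrep("A", n), character(1)),
    file.path(sp_dir, "proteins.fasta")
  )
  write_domtblout(do.call(rbind, rec$dom), file.path(sp_dir, "domains.domtblout"))
  write_blast_tab(do.call(rbind, rec$hom), file.path(sp_dir, "homology.tsv"))
  ids <- rec$fasta_id[o]
  utils::write.table(
    data.frame(
      transcript_id = ids,
      annotation_family = vapply(ids, function(id) {
        a <- rec$ann[[id]]
        if (is.null(a)) "" else a
      }, character(1)),
      stringsAsFactors = FALSE
    ),
    file.path(sp_dir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      transcript_id = ids,
      total_counts = vapply(ids, function(id) rec$cnt[[id]], numeric(1)),
      stringsAsFactors = FALSE
    ),
    file.path(sp_dir, "counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(
      transcript_id = ids,
      taxon_label = vapply(ids, function(id) rec$tax[[id]], character(1)),
      stringsAsFactors = FALSE
    ),
    file.path(sp_dir, "taxonomy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  do.call(rbind, rec$truth)
}
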