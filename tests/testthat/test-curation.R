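test_that("assembler headers parse into cluster coordinates", {
  h <- parse_assembler_header("TRINITY_DN513_c0_g2_i3")
  expect_equal(h$component, "DN513_c0")
  expect_equal(h$gene_index, "g2")
  expect_equal(h$isoform_index, "i3")
  # isoforms of one gene vs paralogs
  two <- parse_assembler_header(c("TRINITY_DN513_c0_g2_i1", "TRINITY_DN513_c0_g2_i3"))
  expect_equal(two$component[1], two$component[2])
  expect_equal(two$gene_index[1], two$gene_index[2])
  par <- parse_assembler_header(c("TRINITY_DN513_c0_g1_i1", "TRINITY_DN513_c0_g2_i1"))
  expect_false(par$gene_index[1] == par$gene_index[2])
  expect_error(
    parse_assembler_header("DN513_c0_g1"),
    "malformed assembler header: DN513_c0_g1"
  )
  # configurable prefix
  h2 <- parse_assembler_header("ASM_DN1_c2_g1_i1", prefix = "ASM_")
  expect_equal(h2$component, "DN1_c2")
})

test_that("taxonomy filter keeps host lineages and honours the unassigned default", {
  cfg <- curation_config()
  expect_true(taxonomy_filter("Metazoa; Insecta; Blattodea", cfg))
  expect_false(taxonomy_filter("Bacteria; Proteobacteria", cfg))
  expect_true(taxonomy_filter("unassigned", cfg))
  strict <- curation_config(keep_unassigned_taxa = FALSE)
  expect_false(taxonomy_filter("unassigned", strict))
})

test_that("domain assignment takes the best accepted hit with declared tie-breaks", {
  defs <- default_family_definitions()
  cfg <- curation_config()
  hit <- function(protein, domain, ie, score) {
    data.frame(
      protein = protein, domain = domain, i_evalue = ie, score = score,
      env_from = 1L, env_to = 50L, stringsAsFactors = FALSE
    )
  }
  # single mapping
  one <- assign_family_by_domain(hit("t1", "Lectin_C", 1e-20, 90), defs, cfg)
  expect_equal(unname(one["t1"]), "CTL")
  # above the E-value bar: no family
  none <- assign_family_by_domain(hit("t1", "Lectin_C", 1e-3, 90), defs, cfg)
  expect_false("t1" %in% names(none))
  # best i-E-value wins across competing families
  both <- assign_family_by_domain(
    rbind(hit("t1", "Lectin_C", 1e-30, 50), hit("t1", "CLIP_SP", 1e-8, 99)),
    defs, cfg
  )
  expect_equal(unname(both["t1"]), "CTL")
  # exact E-value tie: higher score wins (verified both orderings)
  for (ord in list(1:2, 2:1)) {
    tie_hits <- rbind(
      hit("t1", "Lectin_C", 1e-10, 40),
      hit("t1", "CLIP_SP", 1e-10, 80)
    )[ord, ]
    tie <- assign_family_by_domain(tie_hits, defs, cfg)
    expect_equal(unname(tie["t1"]), "CLIP")
  }
  # a domain claimed by two families is a configuration error
  bad_defs <- rbind(defs, data.frame(
    family = "CTL2", class = "receptor", is_amp = FALSE, domains = "Lectin_C"
  ))
  expect_error(
    assign_family_by_domain(hit("t1", "Lectin_C", 1e-20, 90), bad_defs, cfg),
    "more than one family"
  )
})

test_that("homology and annotation agreement follow the declared defaults", {
  cfg <- curation_config()
  expect_equal(crosscheck_homology("CTL", "CTL", cfg), "keep")
  expect_equal(crosscheck_homology("CTL", "GNBP", cfg), "family-disagreement")
  expect_equal(crosscheck_homology("CTL", NA, cfg), "no-homology")
  lax <- curation_config(drop_no_homology = FALSE)
  expect_equal(crosscheck_homology("CTL", NA, lax), "keep")

  expect_equal(crosscheck_annotation("CTL", "CTL"), "keep")
  expect_equal(crosscheck_annotation("CTL", "CLIP"), "annotation-mismatch")
  expect_equal(crosscheck_annotation("CTL", NA), "keep")
})

test_that("length filter exempts AMP families and passes the boundary", {
  cfg <- curation_config()
  expect_false(length_filter(99, is_amp = FALSE, cfg))
  expect_true(length_filter(45, is_amp = TRUE, cfg))
  expect_true(length_filter(100, is_amp = FALSE, cfg))
})

test_that("representative isoform selection uses length, counts, then name", {
  iso <- function(id, len, cnt, idx) {
    data.frame(
      transcript_id = id, protein_length = len, total_counts = cnt,
      isoform_index = idx, stringsAsFactors = FALSE
    )
  }
  expect_equal(
    select_representative_isoform(rbind(
      iso("a", 120, 10, "i1"), iso("b", 250, 1, "i2")
    )),
    "b"
  )
  expect_equal(
    select_representative_isoform(rbind(
      iso("a", 200, 10, "i1"), iso("b", 200, 40, "i2")
    )),
    "b"
  )
  expect_equal(
    select_representative_isoform(rbind(
      iso("a", 200, 10, "i2"), iso("b", 200, 10, "i1")
    )),
    "b"
  )
  expect_equal(select_representative_isoform(iso("a", 100, 1, "i1")), "a")
  expect_error(select_representative_isoform(iso("a", 1, 1, "i1")[0, ]), "no isoforms")
})

test_that("expression flag fires below five counts and is off in genome mode", {
  cfg <- curation_config()
  expect_true(expression_flag(4, cfg))
  expect_false(expression_flag(5, cfg))
  expect_true(expression_flag(0, cfg))
  gm <- curation_config(genome_mode = TRUE)
  expect_false(expression_flag(0, gm))
})

test_that("cascade reproduces the planted truth exactly on the fixture", {
  d <- withr::local_tempdir()
  fx <- generate_transcriptome_fixture(d, seed = 101)
  res <- curate_directory(d)
  # count matrix equals the planted expectation
  expect_identical(res$matrix, fx$expected_matrix)
  # decision log partitions the input transcripts
  expect_equal(nrow(res$decisions), nrow(fx$truth))
  expect_false(anyDuplicated(res$decisions[, c("species", "transcript_id")]) > 0)
  # precision and recall are 1 for every decoy class the cascade handles
  m <- merge(fx$truth, res$decisions, by = c("species", "transcript_id"))
  expect_equal(nrow(m), nrow(fx$truth))
  for (st in unique(fx$truth$stage)) {
    planted <- m$stage.x == st
    called <- m$stage.y == st
    expect_equal(m$stage.y[planted], m$stage.x[planted]) # recall
    expect_equal(m$stage.x[called], m$stage.y[called]) # precision
  }
  expect_equal(m$fate.x, m$fate.y)
})

test_that("cascade is idempotent on its own accepted set", {
  d <- withr::local_tempdir()
  generate_transcriptome_fixture(d, seed = 55, species = "Blattella_germanica")
  b <- read_evidence_bundle(file.path(d, "Blattella_germanica"))
  defs <- read_family_definitions(file.path(d, "families.tsv"))
  first <- run_cascade(b, defs)
  kept_ids <- first$decisions$transcript_id[
    first$decisions$fate %in% c("accepted", "flagged")
  ]
  b2 <- b
  b2$transcripts <- b$transcripts[b$transcripts$transcript_id %in% kept_ids, ]
  b2$domain_hits <- b$domain_hits[b$domain_hits$protein %in% kept_ids, ]
  b2$homology_hits <- b$homology_hits[b$homology_hits$qseqid %in% kept_ids, ]
  second <- run_cascade(b2, defs)
  expect_identical(second$matrix, first$matrix)
  expect_setequal(
    second$decisions$transcript_id[second$decisions$fate %in% c("accepted", "flagged")],
    kept_ids
  )
})

test_that("removing the isoform collapse can only increase counts", {
  d <- withr::local_tempdir()
  generate_transcriptome_fixture(d, seed = 77, species = "Blattella_germanica")
  b <- read_evidence_bundle(file.path(d, "Blattella_germanica"))
  defs <- read_family_definitions(file.path(d, "families.tsv"))
  with_collapse <- run_cascade(b, defs, curation_config())
  without <- run_cascade(b, defs, curation_config(genome_mode = TRUE))
  expect_true(all(without$matrix >= with_collapse$matrix))
})

test_that("genome mode equals transcriptome mode on single-isoform input", {
  d <- withr::local_tempdir()
  generate_transcriptome_fixture(d,
    seed = 78, species = "Blattella_germanica",
    plant = fixture_plant(n_true_genes = 5, max_isoforms = 1, decoys = c(fragment = 1))
  )
  b <- read_evidence_bundle(file.path(d, "Blattella_germanica"))
  defs <- read_family_definitions(file.path(d, "families.tsv"))
  tm <- run_cascade(b, defs, curation_config())
  gm <- run_cascade(b, defs, curation_config(genome_mode = TRUE))
  expect_identical(tm$matrix, gm$matrix)
})
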