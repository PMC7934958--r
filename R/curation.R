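## The conservative immune-gene identification cascade: from per-transcript
## evidence to a curated families x species gene count matrix. Filters are
## applied in a fixed order (taxonomy -> domain family assignment ->
## homology agreement -> annotation agreement -> length -> isoform
## collapse -> expression flag) and every transcript receives exactly one
## logged decision.

#' Curation configuration
#'
#' @param domain_ievalue_max largest accepted per-domain independent
#'   E-value (default 1e-5).
#' @param domain_score_min optional per-domain bit score floor
#'   (`NULL` = none).
#' @param min_length length floor in amino acids for non-AMP families
#'   (default 100).
#' @param low_count_threshold genes with total counts below this are
#'   flagged for review (default 5).
#' @param keep_unassigned_taxa keep transcripts with taxon label
#'   `"unassigned"` (default `TRUE`).
#' @param drop_no_homology drop candidates without any homology hit
#'   (conservative default `TRUE`): the agreement filter needs a
#'   comparison object.
#' @param metazoa_token lineage substring identifying host transcripts.
#' @param genome_mode skip the isoform collapse and the expression flag
#'   (inputs are gene models, not assembled transcripts).
#' @param strict_flags drop low-expression genes instead of flagging them.
#' @param header_prefix assembler header prefix.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(domain_ievalue_max = 1e-5,
                            domain_score_min = NULL,
                            min_length = 100L,
                            low_count_threshold = 5,
                            keep_unassigned_taxa = TRUE,
                            drop_no_homology = TRUE,
                            metazoa_token = "Metazoa",
                            genome_mode = FALSE,
                            strict_flags = FALSE,
                            header_prefix = "TRINITY_") {
  structure(
    list(
      domain_ievalue_max = domain_ievalue_max,
      domain_score_min = domain_score_min,
      min_length = as.integer(min_length),
      low_count_threshold = low_count_threshold,
      keep_unassigned_taxa = keep_unassigned_taxa,
      drop_no_homology = drop_no_homology,
      metazoa_token = metazoa_token,
      genome_mode = genome_mode,
      strict_flags = strict_flags,
      header_prefix = header_prefix
    ),
    class = "curation_config"
  )
}

#' Parse assembler-convention transcript headers
#'
#' Headers of the form `TRINITY_DN<n>_c<k>_g<j>_i<m>` carry the assembly
#' graph coordinates used to disambiguate isoforms from paralogs:
#' transcripts sharing (component, gene index) are isoforms of one gene;
#' equal component but different gene index are distinct genes (putative
#' paralogs).
#'
#' @param ids character vector of transcript identifiers.
#' @param prefix assembler prefix (default `"TRINITY_"`).
#' @return data.frame with `component` (e.g. `"DN513_c0"`), `gene_index`
#'   (`"g2"`), `isoform_index` (`"i3"`).
#' @examples
#' parse_assembler_header("TRINITY_DN513_c0_g2_i3")
#' @export
parse_assembler_header <- function(ids, prefix = "TRINITY_") {
  pat <- paste0(
    "^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", prefix),
    "(DN[0-9]+)_(c[0-9]+)_(g[0-9]+)_(i[0-9]+)$"
  )
  ok <- grepl(pat, ids)
  if (!all(ok)) {
    stop("malformed assembler header: ", ids[!ok][1])
  }
  data.frame(
    component = paste0(sub(pat, "\\1", ids), "_", sub(pat, "\\2", ids)),
    gene_index = sub(pat, "\\3", ids),
    isoform_index = sub(pat, "\\4", ids),
    stringsAsFactors = FALSE
  )
}

#' Taxonomy (host) filter
#'
#' Keeps transcripts whose lineage string contains the host token
#' (default `"Metazoa"`); `"unassigned"` labels are kept or dropped per
#' configuration (kept by default).
#'
#' @param taxon_labels character vector of lineage strings.
#' @param config a [curation_config()].
#' @return logical keep vector.
#' @export
taxonomy_filter <- function(taxon_labels, config = curation_config()) {
  unassigned <- taxon_labels == "unassigned" | is.na(taxon_labels)
  host <- grepl(config$metazoa_token, taxon_labels, fixed = TRUE)
  host | (unassigned & config$keep_unassigned_taxa)
}

#' Assign a candidate family from domain hits
#'
#' The best accepted domain hit (independent E-value at or below the
#' threshold, optional score floor) maps through the family definitions to
#' one candidate family. Best = smallest i-E-value; ties by higher score,
#' then domain name. Transcripts with no surviving hit get `NA`.
#'
#' @param domain_hits data.frame as [read_domtblout()].
#' @param defs family definitions ([default_family_definitions()] format).
#' @param config a [curation_config()].
#' @return named character vector: candidate family (or `NA`) per protein
#'   appearing in `domain_hits`.
#' @export
assign_family_by_domain <- function(domain_hits, defs,
                                    config = curation_config()) {
  map <- domain_family_map(defs)
  h <- domain_hits[domain_hits$domain %in% names(map), , drop = FALSE]
  h <- h[h$i_evalue <= config$domain_ievalue_max, , drop = FALSE]
  if (!is.null(config$domain_score_min)) {
    h <- h[h$score >= config$domain_score_min, , drop = FALSE]
  }
  if (nrow(h) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  h <- h[order(h$protein, h$i_evalue, -h$score, h$domain), , drop = FALSE]
  best <- h[!duplicated(h$protein), , drop = FALSE]
  stats::setNames(unname(map[best$domain]), best$protein)
}

# best homology hit per query: highest bitscore, ties by lower E-value,
# then subject id
best_homology_hits <- function(homology_hits) {
  if (nrow(homology_hits) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  h <- homology_hits[
    order(
      homology_hits$qseqid, -homology_hits$bitscore,
      homology_hits$evalue, homology_hits$sseqid
    ), ,
    drop = FALSE
  ]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  stats::setNames(best$family, best$qseqid)
}

#' Homology agreement check
#'
#' A candidate is kept only when its best homology hit against the immune
#' reference set carries the same family label as the domain-based
#' assignment. Candidates with no homology hit are dropped by default
#' (configurable): agreement cannot be established without a hit.
#'
#' @param candidate_family candidate family label.
#' @param best_hit_family family of the best homology hit, or `NA`.
#' @param config a [curation_config()].
#' @return `"keep"`, `"family-disagreement"` or `"no-homology"`.
#' @export
crosscheck_homology <- function(candidate_family, best_hit_family,
                                config = curation_config()) {
  ifelse(
    is.na(best_hit_family),
    ifelse(config$drop_no_homology, "no-homology", "keep"),
    ifelse(best_hit_family == candidate_family, "keep", "family-disagreement")
  )
}

#' External annotation agreement check
#'
#' Drops a candidate whose external (e.g. assembly-annotation) best-hit
#' family is present and differs from the candidate family; absence of an
#' annotation is not disagreement.
#'
#' @param candidate_family candidate family label.
#' @param annotation_family external annotation family, or `NA`.
#' @return `"keep"` or `"annotation-mismatch"`.
#' @export
crosscheck_annotation <- function(candidate_family, annotation_family) {
  ifelse(
    is.na(annotation_family) | annotation_family == candidate_family,
    "keep", "annotation-mismatch"
  )
}

#' Protein length filter
#'
#' Drops predicted proteins shorter than the length floor (default 100
#' amino acids) unless the family is an antimicrobial peptide family,
#' whose mature products are legitimately short.
#'
#' @param protein_length length in amino acids.
#' @param is_amp is the assigned family an AMP family?
#' @param config a [curation_config()].
#' @return logical keep vector.
#' @export
length_filter <- function(protein_length, is_amp,
                          config = curation_config()) {
  protein_length >= config$min_length | is_amp
}

#' Select the representative isoform of a gene
#'
#' Among the surviving isoforms of one gene (same component and gene
#' index), the representative is the longest predicted protein; ties are
#' broken by higher total counts, then lexicographically smallest isoform
#' index.
#'
#' @param isoforms data.frame with columns `transcript_id`,
#'   `protein_length`, `total_counts`, `isoform_index`.
#' @return the representative `transcript_id`.
#' @export
select_representative_isoform <- function(isoforms) {
  if (nrow(isoforms) == 0) stop("no isoforms supplied")
  o <- order(
    -isoforms$protein_length, -isoforms$total_counts,
    isoforms$isoform_index
  )
  isoforms$transcript_id[o[1]]
}

#' Low-expression flag
#'
#' Genes whose total read count falls below the threshold (default 5) are
#' flagged for manual review; they stay in the count matrix unless strict
#' mode drops them. Disabled in genome mode.
#'
#' @param total_counts gene-level total counts.
#' @param config a [curation_config()].
#' @return logical flagged vector.
#' @export
expression_flag <- function(total_counts, config = curation_config()) {
  if (config$genome_mode) {
    return(rep(FALSE, length(total_counts)))
  }
  total_counts < config$low_count_threshold
}

decision <- function(id, fate, stage, family = NA_character_) {
  data.frame(
    transcript_id = id, fate = fate, stage = stage, family = family,
    stringsAsFactors = FALSE
  )
}

#' Run the curation cascade on one or more evidence bundles
#'
#' Applies, in order: taxonomy filter, domain-based family assignment,
#' homology agreement, annotation agreement, length filter, isoform
#' collapse (skipped in genome mode) and the low-expression flag, then
#' counts distinct accepted genes per family and species.
#'
#' @param bundles one bundle from [read_evidence_bundle()], or a list of
#'   them (one per species).
#' @param defs family definitions.
#' @param config a [curation_config()].
#' @return list with `matrix` (families x species integer count matrix
#'   covering every defined family), `decisions` (one row per transcript:
#'   species, transcript, fate accepted/flagged/dropped, stage, family),
#'   `genes` (gene-level table with representative transcript, counts and
#'   flag), and `flags` (the flagged subset of `genes`).
#' @export
run_cascade <- function(bundles, defs = default_family_definitions(),
                        config = curation_config()) {
  if (!is.null(bundles$transcripts)) bundles <- list(bundles)
  species_names <- vapply(bundles, function(b) b$species, character(1))
  if (anyDuplicated(species_names)) stop("duplicate species in bundles")
  all_dec <- list()
  all_genes <- list()
  for (b in bundles) {
    out <- cascade_one_species(b, defs, config)
    out$decisions$species <- b$species
    if (nrow(out$genes) > 0) out$genes$species <- b$species
    all_dec[[b$species]] <- out$decisions
    all_genes[[b$species]] <- out$genes
  }
  decisions <- do.call(rbind, all_dec)
  rownames(decisions) <- NULL
  genes <- do.call(rbind, all_genes)
  rownames(genes) <- NULL
  mat <- matrix(0L, nrow(defs), length(bundles),
    dimnames = list(defs$family, species_names)
  )
  if (!is.null(genes) && nrow(genes) > 0) {
    kept <- genes[genes$fate %in% c("accepted", "flagged"), , drop = FALSE]
    if (nrow(kept) > 0) {
      tab <- table(
        factor(kept$family, levels = defs$family),
        factor(kept$species, levels = species_names)
      )
      mat[] <- as.integer(tab)
    }
  }
  list(
    matrix = mat,
    decisions = decisions[, c("species", "transcript_id", "fate", "stage", "family")],
    genes = genes,
    flags = if (is.null(genes)) NULL else genes[genes$flagged %in% TRUE, , drop = FALSE]
  )
}

cascade_one_species <- function(bundle, defs, config) {
  tx <- bundle$transcripts
  dec <- list()
  drop_ids <- function(ids, stage, family = NA_character_) {
    if (length(ids) > 0) {
      dec[[length(dec) + 1L]] <<- decision(ids, "dropped", stage, family)
    }
    tx[!(tx$transcript_id %in% ids), , drop = FALSE]
  }

  # 1. taxonomy
  keep <- taxonomy_filter(tx$taxon_label, config)
  tx <- drop_ids(tx$transcript_id[!keep], "taxonomy")

  # 2. domain-based family assignment
  fam_by_domain <- assign_family_by_domain(bundle$domain_hits, defs, config)
  tx$family <- unname(fam_by_domain[tx$transcript_id])
  tx <- drop_ids(tx$transcript_id[is.na(tx$family)], "no-domain")

  # 3. homology agreement
  best_hom <- best_homology_hits(bundle$homology_hits)
  verdict <- crosscheck_homology(
    tx$family, unname(best_hom[tx$transcript_id]), config
  )
  for (st in c("no-homology", "family-disagreement")) {
    bad <- tx$transcript_id[verdict == st]
    fam_bad <- tx$family[verdict == st]
    if (length(bad) > 0) {
      dec[[length(dec) + 1L]] <- decision(bad, "dropped", st, fam_bad)
      keep_row <- !(tx$transcript_id %in% bad)
      tx <- tx[keep_row, , drop = FALSE]
      verdict <- verdict[keep_row]
    }
  }

  # 4. annotation agreement
  verdict <- crosscheck_annotation(tx$family, tx$annotation_family)
  bad <- verdict == "annotation-mismatch"
  if (any(bad)) {
    dec[[length(dec) + 1L]] <- decision(
      tx$transcript_id[bad], "dropped", "annotation-mismatch", tx$family[bad]
    )
    tx <- tx[!bad, , drop = FALSE]
  }

  # 5. length (AMP families exempt)
  amp <- stats::setNames(defs$is_amp, defs$family)
  keep <- length_filter(tx$protein_length, amp[tx$family], config)
  if (any(!keep)) {
    dec[[length(dec) + 1L]] <- decision(
      tx$transcript_id[!keep], "dropped", "length", tx$family[!keep]
    )
    tx <- tx[keep, , drop = FALSE]
  }

  # 6. isoform collapse (one representative per component/gene index)
  tx$gene_key <- paste(tx$component, tx$gene_index, sep = "_")
  if (!config$genome_mode && nrow(tx) > 0) {
    reps <- vapply(
      split(tx, tx$gene_key),
      select_representative_isoform, character(1)
    )
    redundant <- !(tx$transcript_id %in% reps)
    if (any(redundant)) {
      dec[[length(dec) + 1L]] <- decision(
        tx$transcript_id[redundant], "dropped", "isoform-collapse",
        tx$family[redundant]
      )
    }
  } else {
    reps <- tx$transcript_id
  }

  # 7. gene-level assembly + expression flag
  gene_counts <- tapply(tx$total_counts, tx$gene_key, sum)
  rep_rows <- tx[tx$transcript_id %in% reps, , drop = FALSE]
  genes <- data.frame(
    gene = rep_rows$gene_key,
    family = rep_rows$family,
    representative = rep_rows$transcript_id,
    protein_length = rep_rows$protein_length,
    total_counts = as.numeric(gene_counts[rep_rows$gene_key]),
    stringsAsFactors = FALSE
  )
  genes$flagged <- expression_flag(genes$total_counts, config)
  if (config$strict_flags && any(genes$flagged)) {
    low <- genes$flagged
    dec[[length(dec) + 1L]] <- decision(
      genes$representative[low], "dropped", "low-expression",
      genes$family[low]
    )
    genes <- genes[!low, , drop = FALSE]
  }
  genes$fate <- ifelse(genes$flagged, "flagged", "accepted")
  if (nrow(genes) > 0) {
    dec[[length(dec) + 1L]] <- data.frame(
      transcript_id = genes$representative,
      fate = genes$fate,
      stage = ifelse(genes$flagged, "low-expression", "accepted"),
      family = genes$family,
      stringsAsFactors = FALSE
    )
  }
  decisions <- do.call(rbind, dec)
  if (is.null(decisions)) {
    decisions <- decision(character(0), character(0), character(0))
  }
  if (anyDuplicated(decisions$transcript_id)) {
    stop("internal error: transcript decided twice")
  }
  list(decisions = decisions, genes = genes)
}

#' Curate a directory of per-species evidence bundles
#'
#' Each subdirectory of `root` is read as one species bundle and the
#' cascade is run across all of them.
#'
#' @param root directory whose subdirectories are species bundles.
#' @param defs family definitions (default: `families.tsv` in `root` if
#'   present, else the built-in panel).
#' @param config a [curation_config()].
#' @return as [run_cascade()].
#' @export
curate_directory <- function(root, defs = NULL,
                             config = curation_config()) {
  if (is.null(defs)) {
    ft <- file.path(root, "families.tsv")
    defs <- if (file.exists(ft)) {
      read_family_definitions(ft)
    } else {
      default_family_definitions()
    }
  }
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0) stop("no species subdirectories in ", root)
  bundles <- lapply(dirs, read_evidence_bundle,
    header_prefix = config$header_prefix
  )
  run_cascade(bundles, defs, config)
}
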