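## Readers and writers for the per-species transcript evidence bundle:
## protein FASTA, HMMER per-domain table (domtblout), tabular homology
## hits (12-column BLAST outfmt 6), expression counts, taxonomy labels,
## external annotation labels, and the immune family definition table.

#' Default immune gene family definitions
#'
#' A panel of canonical insect immune gene families with their accepted
#' protein domains, functional class (effector / receptor / signalling)
#' and antimicrobial-peptide flag (AMP families are exempt from the
#' 100-amino-acid length filter). This is a starting panel for synthetic
#' fixtures and examples; real analyses load a curated table with
#' [read_family_definitions()].
#'
#' @return data.frame with columns `family`, `class`, `is_amp`, `domains`
#'   (semicolon-separated accepted domain names).
#' @export
default_family_definitions <- function() {
  def <- function(family, class, is_amp, domains) {
    data.frame(
      family = family, class = class, is_amp = is_amp, domains = domains,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    def("GNBP", "receptor", FALSE, "Glucanase"),
    def("PGRP", "receptor", FALSE, "PGRP"),
    def("CTL", "receptor", FALSE, "Lectin_C"),
    def("galectin", "receptor", FALSE, "Gal_Lectin"),
    def("SCR", "receptor", FALSE, "SRCR"),
    def("nimrod", "receptor", FALSE, "NIM_rep"),
    def("dscam", "receptor", FALSE, "Ig_Dscam"),
    def("toll", "receptor", FALSE, "TIR"),
    def("spaetzle", "signalling", FALSE, "Spaetzle"),
    def("CLIP", "signalling", FALSE, "CLIP_SP;Tryp_CLIP"),
    def("serpin", "signalling", FALSE, "Serpin"),
    def("MyD88", "signalling", FALSE, "Death_MyD88"),
    def("pelle", "signalling", FALSE, "Pkinase_Pelle"),
    def("cactus", "signalling", FALSE, "Ankyrin_Cactus"),
    def("dorsal", "signalling", FALSE, "RHD_Dorsal"),
    def("relish", "signalling", FALSE, "RHD_Rel"),
    def("IMD", "signalling", FALSE, "Death_IMD"),
    def("dredd", "signalling", FALSE, "Peptidase_C14"),
    def("JAK", "signalling", FALSE, "Pkinase_JAK"),
    def("STAT", "signalling", FALSE, "STAT_bind"),
    def("ATG", "signalling", FALSE, "ATG_C"),
    def("TEP", "effector", FALSE, "A2M"),
    def("defensin", "effector", TRUE, "Defensin_ins"),
    def("termicin", "effector", TRUE, "Termicin"),
    def("attacin", "effector", TRUE, "Attacin"),
    def("drosomycin", "effector", TRUE, "Drosomycin"),
    def("diptericin", "effector", TRUE, "Diptericin"),
    def("lysozyme", "effector", FALSE, "Lysozyme"),
    def("TPX", "effector", FALSE, "AhpC_TSA"),
    def("PPO", "effector", FALSE, "Hemocyanin_M"),
    def("transferrin", "effector", FALSE, "Transferrin"),
    def("NOS", "effector", FALSE, "NO_synthase")
  )
}

#' Read / write the immune family definition table
#'
#' TSV with columns `family`, `class` (effector / receptor / signalling),
#' `is_amp` (TRUE/FALSE), `domains` (semicolon-separated domain names).
#'
#' @param path file path.
#' @return data.frame as [default_family_definitions()].
#' @export
read_family_definitions <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  need <- c("family", "class", "is_amp", "domains")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col) > 0) {
    stop("family definition table lacks column(s): ",
      paste(missing_col, collapse = ", "))
  }
  df$is_amp <- as.logical(df$is_amp)
  bad_class <- setdiff(df$class, c("effector", "receptor", "signalling"))
  if (length(bad_class) > 0) {
    stop("unknown family class(es): ", paste(bad_class, collapse = ", "))
  }
  df
}

#' @rdname read_family_definitions
#' @param defs family definition data.frame.
#' @export
write_family_definitions <- function(defs, path) {
  utils::write.table(defs, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

# domain -> family lookup; a domain claimed by two families is a
# configuration error
domain_family_map <- function(defs) {
  doms <- strsplit(defs$domains, ";", fixed = TRUE)
  map <- stats::setNames(
    rep(defs$family, lengths(doms)),
    unlist(doms)
  )
  dup <- unique(names(map)[duplicated(names(map))])
  if (length(dup) > 0) {
    stop(
      "domain(s) mapped to more than one family: ",
      paste(dup, collapse = ", ")
    )
  }
  map
}

#' Read a protein FASTA into id / length pairs
#'
#' Only identifiers (first whitespace-delimited token of the header) and
#' sequence lengths are used downstream; residues themselves never enter
#' the cascade.
#'
#' @param path FASTA file of predicted proteins.
#' @return data.frame with `transcript_id`, `protein_length`.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seq_len_by <- tapply(nchar(lines[!hdr]), grp[!hdr], sum)
  data.frame(
    transcript_id = ids,
    protein_length = as.integer(seq_len_by[as.character(seq_len(sum(hdr)))]),
    stringsAsFactors = FALSE
  )
}

#' Write a protein FASTA
#' @param ids sequence identifiers.
#' @param seqs character vector of residues.
#' @param path output file.
#' @export
write_protein_fasta <- function(ids, seqs, path) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Read a HMMER per-domain hits table (domtblout format)
#'
#' Parses the 22-column whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout` (target = protein, query = domain model).
#'
#' @param path domtblout file.
#' @return data.frame with `protein`, `domain`, `i_evalue` (independent
#'   E-value), `score` (per-domain bit score), `env_from`, `env_to`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(
      protein = character(0), domain = character(0),
      i_evalue = numeric(0), score = numeric(0),
      env_from = integer(0), env_to = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(fields) < 22L)
  if (length(short) > 0) {
    stop("malformed domtblout line ", short[1], " in ", path)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    protein = get(1), domain = get(4),
    i_evalue = as.numeric(get(13)), score = as.numeric(get(14)),
    env_from = as.integer(get(20)), env_to = as.integer(get(21)),
    stringsAsFactors = FALSE
  )
}

#' Write domain hits in domtblout layout
#' @param hits data.frame as returned by [read_domtblout()].
#' @param path output file.
#' @export
write_domtblout <- function(hits, path) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  body <- sprintf(
    "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d 1 %d %d %d 0.90 -",
    hits$protein, hits$env_to + 10L, hits$domain, hits$env_to - hits$env_from + 1L,
    hits$i_evalue, hits$score, hits$i_evalue, hits$i_evalue, hits$score,
    hits$env_to - hits$env_from + 1L, hits$env_to - hits$env_from + 1L,
    hits$env_from, hits$env_to
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tabular homology hits (BLAST outfmt 6, 12 columns)
#'
#' Subjects follow the reference-database convention
#' `<family><sep><reference id>`, from which the hit's family label is
#' extracted.
#'
#' @param path tabular file.
#' @param family_sep separator between family and reference id in the
#'   subject field (default `"|"`).
#' @return data.frame with the 12 standard columns plus `family`.
#' @export
read_blast_tab <- function(path, family_sep = "|") {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols
    ), stringsAsFactors = FALSE)
    df$family <- character(0)
    return(df)
  }
  df <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, col.names = cols
  )
  df$family <- vapply(
    strsplit(df$sseqid, family_sep, fixed = TRUE),
    `[[`, character(1), 1
  )
  df
}

#' Write tabular homology hits (12-column layout)
#' @param hits data.frame with the 12 standard columns.
#' @param path output file.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  utils::write.table(hits[, cols], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

read_two_col_tsv <- function(path, col2, as_num = FALSE) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  names(df) <- c("transcript_id", col2)
  if (as_num) df[[col2]] <- as.numeric(df[[col2]])
  df
}

#' Read per-transcript expression counts (TSV: transcript_id, total_counts)
#' @param path TSV file.
#' @export
read_counts_tsv <- function(path) read_two_col_tsv(path, "total_counts", TRUE)

#' Read per-transcript taxonomy labels (TSV: transcript_id, taxon_label)
#' @param path TSV file.
#' @export
read_taxonomy_tsv <- function(path) read_two_col_tsv(path, "taxon_label")

#' Read per-transcript external annotation families
#' (TSV: transcript_id, annotation_family; empty = no annotation)
#' @param path TSV file.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_two_col_tsv(path, "annotation_family")
  df$annotation_family[df$annotation_family == ""] <- NA_character_
  df
}

#' Read one species' transcript evidence bundle from a directory
#'
#' Expects `proteins.fasta`, `domains.domtblout`, `homology.tsv`,
#' `annotation.tsv`, `counts.tsv` and `taxonomy.tsv` in `dir`, as written
#' by [generate_transcriptome_fixture()] or prepared from real searches.
#'
#' @param dir bundle directory.
#' @param species species name (default: directory basename).
#' @param header_prefix assembler header prefix (see
#'   [parse_assembler_header()]).
#' @param family_sep subject-field separator for [read_blast_tab()].
#' @return list with `species`, `transcripts` (one row per transcript:
#'   id, cluster coordinates, protein length, counts, taxon label,
#'   annotation family), `domain_hits`, `homology_hits`.
#' @export
read_evidence_bundle <- function(dir, species = basename(dir),
                                 header_prefix = "TRINITY_",
                                 family_sep = "|") {
  need <- c(
    "proteins.fasta", "domains.domtblout", "homology.tsv",
    "annotation.tsv", "counts.tsv", "taxonomy.tsv"
  )
  paths <- file.path(dir, need)
  absent <- need[!file.exists(paths)]
  if (length(absent) > 0) {
    stop("bundle ", dir, " lacks file(s): ", paste(absent, collapse = ", "))
  }
  prot <- read_protein_fasta(paths[1])
  hdr <- parse_assembler_header(prot$transcript_id, prefix = header_prefix)
  tx <- cbind(prot, hdr)
  cnt <- read_counts_tsv(paths[5])
  tax <- read_taxonomy_tsv(paths[6])
  ann <- read_annotation_tsv(paths[4])
  tx <- merge(tx, cnt, by = "transcript_id", all.x = TRUE)
  tx <- merge(tx, tax, by = "transcript_id", all.x = TRUE)
  tx <- merge(tx, ann, by = "transcript_id", all.x = TRUE)
  tx$total_counts[is.na(tx$total_counts)] <- 0
  tx$taxon_label[is.na(tx$taxon_label)] <- "unassigned"
  tx <- tx[order(tx$transcript_id), ]
  rownames(tx) <- NULL
  list(
    species = species,
    transcripts = tx,
    domain_hits = read_domtblout(paths[2]),
    homology_hits = read_blast_tab(paths[3], family_sep = family_sep)
  )
}
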