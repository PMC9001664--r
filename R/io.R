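# Readers and writers for V(D)J contig tables and the cohort container.

.tenx_required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                    "productive", "umis")
.airr_required <- c("cell_id", "locus", "v_call", "j_call", "junction",
                    "junction_aa", "productive", "duplicate_count")

.norm_bool <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NONE", "")] <- FALSE
  out
}

.norm_seq <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "None", "NA") | is.na(x)] <- NA_character_
  x
}

#' Read a V(D)J contig annotation table
#'
#' Parses either the 10x Cell Ranger `filtered_contig_annotations.csv` dialect
#' or an AIRR Rearrangement TSV into a contig data frame with one row per
#' assembled contig. Only TRA and TRB records are retained; rows at other loci
#' (IGH, IGK, ...) are dropped and the drop count is reported in the
#' `dropped_by_locus` attribute. Rows whose UMI/duplicate count cannot be
#' parsed are dropped with a warning naming the line, counted in
#' `dropped_malformed`.
#'
#' For the 10x dialect the CDR3 columns may be named either `cdr3`/`cdr3_nt`
#' or `junction_aa`/`junction` (Cell Ranger versions drift); the first match
#' wins. Productivity strings (`"True"`, `"true"`, `"T"`, AIRR `"T"`) are
#' normalized to logicals. Missing CDR3 values become `NA`, never the empty
#' string. Barcodes are opaque: no suffix such as `"-1"` is stripped.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return A data frame of class `tcr_contigs` with columns `barcode`,
#'   `contig_id`, `chain`, `v_gene`, `d_gene`, `j_gene`, `c_gene`, `cdr3_aa`,
#'   `cdr3_nt`, `productive`, `high_confidence`, `umis`, `reads`, in file
#'   order, plus attributes `dropped_by_locus` and `dropped_malformed`.
#' @export
read_contig_table <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (dialect == "tenx_csv") {
    read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    read.csv(path, sep = "\t", colClasses = "character", check.names = FALSE)
  }
  cols <- names(raw)

  if (dialect == "tenx_csv") {
    need <- setdiff(.tenx_required, cols)
    # alternate junction-style headers satisfy the cdr3 requirement
    if ("cdr3" %in% need && "junction_aa" %in% cols) need <- setdiff(need, "cdr3")
    if ("cdr3_nt" %in% need && "junction" %in% cols) need <- setdiff(need, "cdr3_nt")
    if (length(need))
      stop("missing mandatory column(s) in 10x contig table: ",
           paste(need, collapse = ", "), call. = FALSE)
    cdr3_aa <- if ("cdr3" %in% cols) raw$cdr3 else raw$junction_aa
    cdr3_nt <- if ("cdr3_nt" %in% cols) raw$cdr3_nt else raw$junction
    rec <- data.frame(
      barcode = raw$barcode,
      contig_id = if ("contig_id" %in% cols) raw$contig_id else
        paste0(raw$barcode, "_contig_", seq_len(nrow(raw))),
      chain = raw$chain,
      v_gene = .norm_seq(raw$v_gene),
      d_gene = if ("d_gene" %in% cols) .norm_seq(raw$d_gene) else NA_character_,
      j_gene = .norm_seq(raw$j_gene),
      c_gene = if ("c_gene" %in% cols) .norm_seq(raw$c_gene) else NA_character_,
      cdr3_aa = .norm_seq(cdr3_aa),
      cdr3_nt = .norm_seq(cdr3_nt),
      productive = .norm_bool(raw$productive),
      high_confidence = if ("high_confidence" %in% cols)
        .norm_bool(raw$high_confidence) else TRUE,
      umis_raw = raw$umis,
      reads_raw = if ("reads" %in% cols) raw$reads else "0",
      stringsAsFactors = FALSE
    )
  } else {
    need <- setdiff(.airr_required, cols)
    if (length(need))
      stop("missing mandatory column(s) in AIRR table: ",
           paste(need, collapse = ", "), call. = FALSE)
    rec <- data.frame(
      barcode = raw$cell_id,
      contig_id = if ("sequence_id" %in% cols) raw$sequence_id else
        paste0(raw$cell_id, "_seq_", seq_len(nrow(raw))),
      chain = raw$locus,
      v_gene = .norm_seq(raw$v_call),
      d_gene = if ("d_call" %in% cols) .norm_seq(raw$d_call) else NA_character_,
      j_gene = .norm_seq(raw$j_call),
      c_gene = if ("c_call" %in% cols) .norm_seq(raw$c_call) else NA_character_,
      cdr3_aa = .norm_seq(raw$junction_aa),
      cdr3_nt = .norm_seq(raw$junction),
      productive = .norm_bool(raw$productive),
      high_confidence = TRUE,
      umis_raw = raw$duplicate_count,
      reads_raw = if ("consensus_count" %in% cols) raw$consensus_count else "0",
      stringsAsFactors = FALSE
    )
  }

  umis <- suppressWarnings(as.integer(rec$umis_raw))
  reads <- suppressWarnings(as.integer(rec$reads_raw))
  reads[is.na(reads)] <- 0L
  bad <- which(is.na(umis) | is.na(rec$productive))
  dropped_malformed <- length(bad)
  if (length(bad)) {
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    length(bad),
                    paste(head(bad + 1L, 10L), collapse = ", ")),
            call. = FALSE)
    rec <- rec[-bad, , drop = FALSE]
    umis <- umis[-bad]
    reads <- reads[-bad]
  }
  keep <- rec$chain %in% c("TRA", "TRB")
  dropped_locus <- sum(!keep)
  if (dropped_locus)
    message(sprintf("read_contig_table: dropped %d non-TRA/TRB contig(s)",
                    dropped_locus))
  rec <- rec[keep, , drop = FALSE]
  rec$umis <- umis[keep]
  rec$reads <- reads[keep]
  rec$umis_raw <- NULL
  rec$reads_raw <- NULL
  rownames(rec) <- NULL
  if (nrow(rec) == 0L)
    warning("no TRA/TRB contig records parsed from ", path, call. = FALSE)
  structure(rec,
            dropped_by_locus = dropped_locus,
            dropped_malformed = dropped_malformed,
            class = c("tcr_contigs", "data.frame"))
}

# normalize an in-memory 10x-dialect data frame (string flags, cdr3/cdr3_nt
# naming) into the tcr_contigs layout; shared by the simulator path
as_contig_records <- function(df) {
  if (inherits(df, "tcr_contigs")) return(df)
  structure(data.frame(
    barcode = df$barcode,
    contig_id = df$contig_id,
    chain = df$chain,
    v_gene = .norm_seq(df$v_gene),
    d_gene = .norm_seq(df$d_gene),
    j_gene = .norm_seq(df$j_gene),
    c_gene = .norm_seq(df$c_gene),
    cdr3_aa = .norm_seq(if ("cdr3_aa" %in% names(df)) df$cdr3_aa else df$cdr3),
    cdr3_nt = .norm_seq(df$cdr3_nt),
    productive = .norm_bool(df$productive),
    high_confidence = if ("high_confidence" %in% names(df))
      .norm_bool(df$high_confidence) else TRUE,
    umis = as.integer(df$umis),
    reads = as.integer(df$reads),
    stringsAsFactors = FALSE
  ), class = c("tcr_contigs", "data.frame"))
}

#' Export contigs as an AIRR Rearrangement TSV
#'
#' Writes the shared fields of a contig table in AIRR column naming so that
#' [read_contig_table()] with `dialect = "airr_tsv"` round-trips them.
#'
#' @param contigs A contig data frame as returned by [read_contig_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_airr <- function(contigs, path) {
  out <- data.frame(
    cell_id = contigs$barcode,
    sequence_id = contigs$contig_id,
    locus = contigs$chain,
    v_call = contigs$v_gene,
    d_call = contigs$d_gene,
    j_call = contigs$j_gene,
    c_call = contigs$c_gene,
    junction = contigs$cdr3_nt,
    junction_aa = contigs$cdr3_aa,
    productive = ifelse(contigs$productive, "T", "F"),
    duplicate_count = contigs$umis,
    consensus_count = contigs$reads,
    stringsAsFactors = FALSE
  )
  write_table(out, path)
}

#' Load a cohort: sample sheet, per-sample contigs, optional embedding
#'
#' The sample sheet is a CSV with columns `sample_id`, `subject_id`,
#' `timepoint`, `group`, `cmv_status` and optionally `responder` and
#' `contig_file`. Contig files default to `<contig_dir>/<sample_id>.csv`
#' (10x dialect) unless a `contig_file` column names them. The optional
#' embedding TSV has columns `barcode`, `sample_id`, `dim_1..dim_k`, `batch`;
#' embedding rows whose (sample_id, barcode) matches no contig-bearing cell
#' are kept but counted as orphans.
#'
#' @param sample_sheet Path to the sample sheet CSV.
#' @param contig_dir Directory containing one contig file per sample.
#' @param embedding_path Optional path to an embedding TSV.
#' @param dialect Contig file dialect, as in [read_contig_table()].
#' @return A `tcr_cohort` list with elements `samples`, `contigs` (named list
#'   of contig data frames), `embedding` (or `NULL`) and `orphan_barcodes`.
#' @export
load_cohort <- function(sample_sheet, contig_dir, embedding_path = NULL,
                        dialect = "tenx_csv") {
  sheet <- read.csv(sample_sheet, colClasses = "character")
  req <- c("sample_id", "subject_id", "timepoint", "group", "cmv_status")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "), call. = FALSE)
  st <- paste(sheet$subject_id, sheet$timepoint)
  if (anyDuplicated(st))
    stop("duplicate (subject_id, timepoint) pair(s): ",
         paste(unique(st[duplicated(st)]), collapse = "; "), call. = FALSE)
  if (!"responder" %in% names(sheet)) sheet$responder <- "na"

  files <- if ("contig_file" %in% names(sheet)) {
    file.path(contig_dir, sheet$contig_file)
  } else {
    file.path(contig_dir, paste0(sheet$sample_id, ".csv"))
  }
  absent <- !file.exists(files)
  if (any(absent))
    stop("contig file missing for sample(s): ",
         paste(sheet$sample_id[absent], collapse = ", "), call. = FALSE)

  contigs <- setNames(vector("list", nrow(sheet)), sheet$sample_id)
  for (i in seq_len(nrow(sheet))) {
    ctg <- read_contig_table(files[i], dialect)
    if (nrow(ctg) == 0L)
      warning("sample ", sheet$sample_id[i], " has zero contigs; retained",
              call. = FALSE)
    contigs[[i]] <- ctg
    message(sprintf("loaded %s: %d contigs, %d cells", sheet$sample_id[i],
                    nrow(ctg), length(unique(ctg$barcode))))
  }

  embedding <- NULL
  orphans <- character(0)
  if (!is.null(embedding_path)) {
    embedding <- read.csv(embedding_path, sep = "\t")
    known <- unlist(lapply(names(contigs), function(s)
      cell_key(s, unique(contigs[[s]]$barcode))), use.names = FALSE)
    ekeys <- cell_key(embedding$sample_id, embedding$barcode)
    orphans <- ekeys[!ekeys %in% known]
    if (length(orphans))
      message(sprintf("embedding: %d orphan barcode(s) without contigs",
                      length(orphans)))
  }

  structure(list(samples = sheet, contigs = contigs, embedding = embedding,
                 orphan_barcodes = orphans),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("tcr_cohort: %d sample(s), %d subject(s)\n",
              nrow(x$samples), length(unique(x$samples$subject_id))))
  n_cells <- vapply(x$contigs, function(d) length(unique(d$barcode)), integer(1))
  for (i in seq_len(nrow(x$samples)))
    cat(sprintf("  %s (%s, %s): %d contig-bearing cell(s)\n",
                x$samples$sample_id[i], x$samples$subject_id[i],
                x$samples$timepoint[i], n_cells[i]))
  if (!is.null(x$embedding))
    cat(sprintf("  embedding: %d cell(s), %d orphan(s)\n",
                nrow(x$embedding), length(x$orphan_barcodes)))
  invisible(x)
}
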