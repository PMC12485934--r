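#' Predicted-aligned-error matrix
#'
#' Constructs a PAE matrix: an n x n matrix of expected pairwise position
#' errors in Angstrom, as emitted by structure predictors. The matrix is not
#' assumed symmetric. Rows whose diagonal entry exceeds the row's minimum
#' off-diagonal entry are flagged in the `"diag_flag"` attribute rather than
#' rejected (synthetic matrices legitimately carry noisy diagonals).
#'
#' @param values square numeric matrix, entries >= 0 and finite.
#' @return matrix of class `pae_matrix` with attribute `diag_flag`.
#' @export
pae_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("non-square PAE")
  if (!is.numeric(values) || any(!is.finite(values))) stop("PAE entries must be finite numbers")
  if (any(values < 0)) stop("negative PAE entry")
  n <- nrow(values)
  off_min <- vapply(seq_len(n), function(i) min(values[i, -i][is.finite(values[i, -i])], Inf),
                    numeric(1))
  flag <- if (n > 1) diag(values) > off_min else logical(1)
  structure(values, class = c("pae_matrix", "matrix", "array"), diag_flag = flag)
}

#' Read a PAE matrix from predictor JSON
#'
#' Accepts the JSON layouts distributed by public structure-prediction
#' databases: a top-level object (optionally wrapped in a one-element array)
#' holding the square matrix under `predicted_aligned_error` or `pae`.
#' Values and any asymmetry are preserved exactly.
#'
#' @param path path to a JSON file.
#' @return a [pae_matrix()].
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(j)) j <- as.list(j)
  if (!is.null(j$predicted_aligned_error) || !is.null(j$pae)) {
    m <- j$predicted_aligned_error %||% j$pae
  } else if (is.list(j) && length(j) >= 1 && is.list(j[[1]]) &&
             (!is.null(j[[1]]$predicted_aligned_error) || !is.null(j[[1]]$pae))) {
    m <- j[[1]]$predicted_aligned_error %||% j[[1]]$pae
  } else {
    stop("no 'predicted_aligned_error' (or 'pae') key in ", path)
  }
  if (is.list(m)) {
    lens <- lengths(m)
    if (length(unique(lens)) != 1) stop("non-square PAE")
    m <- do.call(rbind, m)
  }
  pae_matrix(m)
}

#' Write a PAE matrix as predictor-style JSON
#'
#' @param pae a [pae_matrix()] (or plain square matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pae <- function(pae, path) {
  m <- unclass(pae)
  attributes(m) <- list(dim = dim(pae))
  jsonlite::write_json(
    list(generator = sub("^# ", "", io_header()),
         predicted_aligned_error = m,
         max_predicted_aligned_error = max(m)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Cross-link table
#'
#' Canonicalizes residue-pair cross-link restraints: the two (protein,
#' residue) endpoints are ordered lexicographically so a link reported in
#' either orientation collapses to the same unordered pair, and exact
#' duplicates are removed with a message.
#'
#' @param df data.frame with columns `protein_a`, `res_a`, `protein_b`,
#'   `res_b` and optionally `score`.
#' @param quiet suppress the duplicate-collapse message.
#' @return data.frame of class `crosslink_table` with one row per unique
#'   unordered link.
#' @export
crosslink_table <- function(df, quiet = FALSE) {
  need <- c("protein_a", "res_a", "protein_b", "res_b")
  if (!all(need %in% names(df))) {
    stop("missing required column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  df$res_a <- as.integer(df$res_a)
  df$res_b <- as.integer(df$res_b)
  if (nrow(df) > 0 && (any(df$res_a < 1) || any(df$res_b < 1))) {
    stop("residue indices must be >= 1")
  }
  if (!"score" %in% names(df)) df$score <- rep(NA_real_, nrow(df))
  # canonical order: endpoint (protein, res) pairs sorted lexicographically
  swap <- df$protein_b < df$protein_a |
    (df$protein_b == df$protein_a & df$res_b < df$res_a)
  if (any(swap)) {
    tmp_p <- df$protein_a[swap]; tmp_r <- df$res_a[swap]
    df$protein_a[swap] <- df$protein_b[swap]; df$res_a[swap] <- df$res_b[swap]
    df$protein_b[swap] <- tmp_p; df$res_b[swap] <- tmp_r
  }
  key <- paste(df$protein_a, df$res_a, df$protein_b, df$res_b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && !quiet) {
    message(sprintf("collapsed %d duplicate cross-link(s); %d unique link(s) kept",
                    sum(dup), sum(!dup)))
  }
  out <- df[!dup, c("protein_a", "res_a", "protein_b", "res_b", "score"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crosslink_table", "data.frame")
  out
}

#' Read a cross-link table from delimited text
#'
#' Expects a header naming the columns `protein_a`, `res_a`, `protein_b`,
#' `res_b` (tab or comma separated; `#` lines are comments). Rows are
#' canonicalized as unordered pairs and exact duplicates collapsed with a
#' logged count. Parsing is strict: a non-integer residue field aborts with
#' the offending line number; rows are never silently dropped.
#'
#' @param path path to the delimited file.
#' @return a [crosslink_table()].
#' @export
read_crosslinks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(body)) stop("no header line in ", path)
  hdr_line <- which(body)[1]
  sep <- if (grepl("\t", lines[hdr_line])) "\t" else ","
  df <- utils::read.delim(text = lines[body], sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_a", "res_a", "protein_b", "res_b")
  if (!all(need %in% names(df))) {
    stop("missing required column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("cross-link file has a header but no data rows")
  }
  for (col in c("res_a", "res_b")) {
    bad <- suppressWarnings(is.na(as.integer(df[[col]]))) & nzchar(df[[col]])
    bad <- bad | !grepl("^\\s*[0-9]+\\s*$", df[[col]])
    if (any(bad)) {
      line_no <- which(body)[1 + which(bad)[1]]  # header offset
      stop(sprintf("non-integer %s value '%s' at line %d of %s",
                   col, df[[col]][which(bad)[1]], line_no, path))
    }
  }
  n_in <- nrow(df)
  out <- crosslink_table(df)
  message(sprintf("read %d row(s): %d parsed, 0 rejected", n_in, n_in))
  out
}

#' Write a cross-link table as tab-delimited text
#'
#' @param links a [crosslink_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosslinks <- function(links, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header(), con)
  utils::write.table(as.data.frame(links), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a domain partition as a segment table
#'
#' Tab-delimited rows `(domain_id, start, end)`, one per maximal contiguous
#' segment, sorted by domain then start. [read_segments()] is the exact
#' inverse (the residue count is recorded in a comment so trailing linker
#' residues survive the round trip).
#'
#' @param partition a [domain_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(partition, path) {
  seg <- segments_of(partition)$segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header(), con)
  writeLines(sprintf("# residues %d", length(partition)), con)
  utils::write.table(seg[order(seg$domain, seg$start), ], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment table into a domain partition
#'
#' @param path path to a tab-delimited file with columns `domain`, `start`,
#'   `end` (`#` lines are comments; a `# residues N` comment fixes the
#'   chain length, otherwise the largest `end` is used).
#' @return a [domain_partition()].
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- NA_integer_
  res_line <- grep("^#\\s*residues\\s+[0-9]+", lines, value = TRUE)
  if (length(res_line)) n <- as.integer(sub("^#\\s*residues\\s+", "", res_line[1]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.delim(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- sub("^domain_id$", "domain", names(df))
  stopifnot(all(c("domain", "start", "end") %in% names(df)))
  partition_from_segments(df, n = if (is.na(n)) max(df$end) else n)
}
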