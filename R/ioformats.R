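#' Read and write probe-level acetylation tables
#'
#' Tables are plain TSV (UTF-8, no index column) with columns `probe_id`,
#' `gene_id`, `offset_bp`, `day`, `replicate`, `signal`. Control probes carry
#' `.` in `gene_id` and `offset_bp` (read back as `NA`). `offset_bp` is the
#' signed distance to the TSS, oriented 5'->3' along the gene (0 = TSS,
#' positive = downstream). Round trips are bit-exact on canonicalized tables.
#' No replicate averaging happens here.
#'
#' @param path File path.
#' @return `read_probe_table` returns a validated data.frame.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", colClasses = list(
    probe_id = "character", gene_id = "character"),
    stringsAsFactors = FALSE)
  validate_probe_table(df)
}

#' @rdname read_probe_table
#' @param probe_table A probe table data.frame.
#' @export
write_probe_table <- function(probe_table, path) {
  validate_probe_table(probe_table)
  utils::write.table(probe_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

validate_probe_table <- function(df) {
  check_columns(df, c("probe_id", "gene_id", "offset_bp", "day", "replicate",
                      "signal"), "probe table")
  if (nrow(df) == 0L) return(df)
  if (!is.numeric(df$signal)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$signal))))[1]
    stop(sprintf("non-numeric signal at row %d", bad), call. = FALSE)
  }
  key <- paste(df$probe_id, df$day, df$replicate, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("duplicated (probe_id, day, replicate) key: %s",
                 key[dup[1]]), call. = FALSE)
  }
  df
}

#' Read and write gene-expression tables
#'
#' TSV with columns `gene_id`, `day`, `replicate`, `expression` (log scale).
#' Validates key uniqueness and that day 0 is present for every gene.
#'
#' @param path File path.
#' @export
read_expr_table <- function(path) {
  df <- utils::read.delim(path, na.strings = ".", colClasses = list(
    gene_id = "character"), stringsAsFactors = FALSE)
  validate_expr_table(df)
}

#' @rdname read_expr_table
#' @param expr_table An expression table data.frame.
#' @export
write_expr_table <- function(expr_table, path) {
  validate_expr_table(expr_table)
  utils::write.table(expr_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

validate_expr_table <- function(df) {
  check_columns(df, c("gene_id", "day", "replicate", "expression"),
                "expression table")
  if (nrow(df) == 0L) return(df)
  key <- paste(df$gene_id, df$day, df$replicate, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("duplicated (gene_id, day, replicate) key: %s", key[dup[1]]),
         call. = FALSE)
  }
  no0 <- setdiff(df$gene_id, df$gene_id[df$day == 0])
  if (length(no0) > 0L) {
    stop(sprintf("%d gene(s) lack a day-0 measurement (first: %s)",
                 length(no0), no0[1]), call. = FALSE)
  }
  df
}

#' Read and write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member order is
#' preserved; round trips are identical.
#'
#' @param path File path.
#' @return A named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- which(duplicated(nm))
  if (length(dup) > 0L) {
    stop(sprintf("duplicated gene-set name: %s", nm[dup[1]]), call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors; an optional
#'   `descriptions` attribute (named character) supplies the second column.
#' @export
write_gmt <- function(gene_sets, path) {
  if (length(gene_sets) > 0 && is.null(names(gene_sets))) {
    stop("gene sets must be named", call. = FALSE)
  }
  if (any(vapply(gene_sets, length, 1L) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  desc <- attr(gene_sets, "descriptions") %||%
    stats::setNames(rep("", length(gene_sets)), names(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter genes by in-window probe support
#'
#' Retains exactly the genes with strictly more than `min_probes` distinct
#' probes within `window_bp` of the TSS (the quality filter applied before
#' any downstream analysis); control probes pass through untouched. The
#' operation is idempotent.
#'
#' @param probe_table A probe table (see [read_probe_table()]).
#' @param min_probes Genes must have strictly more than this many in-window
#'   probes to survive.
#' @param window_bp Half-width of the window around the TSS used to count.
#' @return The filtered probe table.
#' @export
filter_genes <- function(probe_table, min_probes = 10, window_bp = 3500) {
  validate_probe_table(probe_table)
  gp <- probe_table[!is.na(probe_table$gene_id), , drop = FALSE]
  inw <- gp[abs(gp$offset_bp) <= window_bp, c("gene_id", "probe_id")]
  inw <- unique(inw)
  counts <- table(inw$gene_id)
  keep <- names(counts)[counts > min_probes]
  probe_table[is.na(probe_table$gene_id) | probe_table$gene_id %in% keep, ,
              drop = FALSE]
}

#' Average replicate measurements
#'
#' Collapses a probe or expression table to one row per (id, day) by
#' averaging over replicates; the `replicate` column is set to 1.
#'
#' @param tbl A probe table or expression table.
#' @return The replicate-averaged table.
#' @export
average_replicates <- function(tbl) {
  if ("signal" %in% names(tbl)) {
    key <- paste(tbl$probe_id, tbl$day, sep = "|")
    first <- !duplicated(key)
    out <- tbl[first, , drop = FALSE]
    out$signal <- as.numeric(tapply(tbl$signal, key, mean)[key[first]])
    out$replicate <- 1L
  } else {
    key <- paste(tbl$gene_id, tbl$day, sep = "|")
    first <- !duplicated(key)
    out <- tbl[first, , drop = FALSE]
    out$expression <- as.numeric(tapply(tbl$expression, key, mean)[key[first]])
    out$replicate <- 1L
  }
  rownames(out) <- NULL
  out
}
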