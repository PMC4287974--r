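#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; the
#' body is numeric log2 expression. `orientation = "samples_in_rows"`
#' transposes after reading.
#'
#' @param path Path to a TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param groups Optional named character vector of sample group labels.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows",
                                                "samples_in_rows"),
                                groups = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs id column plus data", call. = FALSE)
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row %d ('%s'), column '%s' in %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]], path),
         call. = FALSE)
  }
  m <- matrix(num, nrow = nrow(body),
              dimnames = list(ids, colnames(body)))
  if (orientation == "samples_in_rows") m <- t(m)
  expression_matrix(m, groups = groups)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path; genes in rows, first column `gene_id`.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read signed gene signatures from a GMT file
#'
#' Standard GMT lines (name, description, tab-separated genes). Sets whose
#' names pair up as `NAME_UP` / `NAME_DN` (case-insensitive suffix) are
#' merged into one signed signature; an unpaired set becomes a signature
#' with an empty complement (an unsuffixed set is treated as all-up).
#'
#' @param path Path to a GMT file.
#' @return Named list of [signed_signature()] objects.
#' @export
read_gmt_signed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  up <- list(); dn <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60), call. = FALSE)
    }
    set_name <- parts[1]
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (grepl("_up$", set_name, ignore.case = TRUE)) {
      up[[sub("_up$", "", set_name, ignore.case = TRUE)]] <- genes
    } else if (grepl("_dn$", set_name, ignore.case = TRUE)) {
      dn[[sub("_dn$", "", set_name, ignore.case = TRUE)]] <- genes
    } else {
      up[[set_name]] <- genes
    }
  }
  sig_names <- union(names(up), names(dn))
  sigs <- lapply(sig_names, function(nm) {
    signed_signature(nm,
                     up = if (nm %in% names(up)) up[[nm]] else character(),
                     down = if (nm %in% names(dn)) dn[[nm]] else character())
  })
  stats::setNames(sigs, sig_names)
}

#' Write signed signatures as GMT
#'
#' Each signature becomes a `NAME_UP` and a `NAME_DN` line (empty sides are
#' skipped).
#'
#' @param sigs A [signed_signature()] or list of them.
#' @param path Output path.
#' @export
write_gmt_signed <- function(sigs, path) {
  if (inherits(sigs, "signed_signature")) sigs <- list(sigs)
  lines <- character()
  for (s in sigs) {
    if (length(s$up) > 0) {
      lines <- c(lines, paste(c(paste0(s$name, "_UP"), "up-regulated", s$up),
                              collapse = "\t"))
    }
    if (length(s$down) > 0) {
      lines <- c(lines, paste(c(paste0(s$name, "_DN"), "down-regulated",
                                s$down), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical cohort from TSV
#'
#' Expects columns `sample`, `time`, `event`, `subtype`. Rows with a missing
#' time or event are dropped with a warning reporting the count; a negative
#' time is an error.
#'
#' @param path Path to a TSV file.
#' @return A [clinical_cohort()].
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("clinical TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"subtype" %in% names(df)) df$subtype <- "unknown"
  keep <- !is.na(df$time) & !is.na(suppressWarnings(as.numeric(df$time))) &
    !is.na(df$event) & df$event != ""
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with missing time/event excluded from ",
            path, call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  clinical_cohort(df$sample, as.numeric(df$time), as.numeric(df$event),
                  df$subtype)
}

#' Write a clinical cohort to TSV
#'
#' @param cohort A [clinical_cohort()].
#' @param path Output path.
#' @export
write_clinical_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  out <- as.data.frame(cohort)
  names(out)[names(out) == "sample_id"] <- "sample"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
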