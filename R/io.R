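#' Read a TSV matrix with validation
#'
#' Reads a tab-separated matrix (header row = column ids, first column = row
#' ids, missing values as the literal `NA`) with the validation downstream
#' stages rely on: ragged rows are reported with their line number and
#' duplicate row/column ids are an error. Lines starting with `#` are
#' metadata comments and skipped.
#'
#' @param path File path.
#' @param orientation `"rows"` (default, rows are the first-axis ids) or
#'   `"transpose"` to flip the matrix after reading.
#'
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, orientation = c("rows", "transpose")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) abort("empty file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(parts[[1]])
  bad <- which(lengths(parts) != width)
  if (length(bad)) {
    abort(sprintf("ragged row at line %d: expected %d fields, found %d",
                  line_no[bad[1]], width, length(parts[[bad[1]]])))
  }
  header <- parts[[1]][-1]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate column ids: ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  body <- parts[-1]
  row_ids <- vapply(body, `[[`, "", 1)
  if (anyDuplicated(row_ids)) {
    abort(paste0("duplicate row ids: ",
                 paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  }
  m <- matrix(NA_real_, length(body), width - 1L,
              dimnames = list(row_ids, header))
  for (i in seq_along(body)) {
    v <- body[[i]][-1]
    v[v == "NA"] <- NA
    m[i, ] <- as.numeric(v)
  }
  if (orientation == "transpose") t(m) else m
}

#' Write a matrix as validated TSV
#'
#' Inverse of [read_matrix_tsv()]: header row of column ids, first column of
#' row ids, `NA` for missing.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_name Name of the id column in the header.
#' @param comment Optional character vector of metadata lines (written as
#'   `#`-prefixed comments).
#'
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id", comment = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_name, colnames(m)), collapse = "\t"), con)
  fmt <- function(x) {
    out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
    out[is.na(x)] <- "NA"
    out
  }
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then the gene symbols. Fewer than three fields is an error; duplicate
#' genes within a set are deduplicated with a warning.
#'
#' @param path File path.
#'
#' @return Tibble: `name`, `description`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]))
  }
  tibble::tibble(
    name = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    genes = purrr::map2(parts, seq_along(parts), function(p, i) {
      g <- p[-(1:2)]
      if (anyDuplicated(g)) {
        warn(sprintf("duplicate genes in set `%s`; deduplicated", p[1]))
        g <- unique(g)
      }
      g
    })
  )
}

#' Write gene sets as GMT
#'
#' @param sets Tibble with `name`, `description` and a `genes` list column.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(name, description, genes, ...) {
    paste(c(name, description, genes), collapse = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# stage artifact writers: plain TSV with a reproducibility comment header
artifact_header <- function(seed, cfg) {
  c(sprintf("irfinger %s", as.character(packageVersion("irfinger"))),
    sprintf("seed=%s", seed),
    sprintf("config_hash=%s", rlang::hash(cfg)))
}

write_artifact <- function(df, path, seed, cfg) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(paste0("# ", artifact_header(seed, cfg)), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_artifact <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
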