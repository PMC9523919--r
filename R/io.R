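#' Read a labelled numeric matrix from TSV
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers; the body must be numeric. Empty cells become `NA` (missing is
#' preserved, never zeroed).
#'
#' @param path Path to a TSV file.
#' @param value_kind Label used in error messages (e.g. "dependency score").
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path, value_kind = "value") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (ncol(raw) < 2) abort("matrix TSV needs a row-identifier column plus data columns")
  row_ids <- raw[[1]]
  dup <- row_ids[duplicated(row_ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicated row identifier: ", dup[[1]]))
  }
  col_ids <- names(raw)[-1]
  dupc <- col_ids[duplicated(col_ids)]
  if (length(dupc) > 0) abort(paste0("duplicated column identifier: ", dupc[[1]]))
  body <- as.matrix(raw[, -1, drop = FALSE])
  body[body == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric %s at row '%s', column '%s'",
                  value_kind, row_ids[bad[1, 1]], col_ids[bad[1, 2]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  num
}

#' Write a labelled numeric matrix to TSV
#'
#' Inverse of [read_matrix()]: `NA` entries become empty cells.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the row-identifier column.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  tbl <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(tbl, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a mutation table from TSV
#'
#' Columns `sample`, `gene`, `mutation_class` are required; unknown classes
#' are mapped to `"other"` and silent calls are flagged non-altering.
#'
#' @inheritParams read_matrix
#' @param altering_classes Passed to [mutation_catalog()].
#' @return A [mutation_catalog()].
#' @export
read_mutations <- function(path, altering_classes = setdiff(MUTATION_CLASSES, "silent")) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample", "gene", "mutation_class")
  if (!all(need %in% names(tbl))) {
    abort(paste0("mutation TSV must have header: ", paste(need, collapse = "\t")))
  }
  mutation_catalog(tbl, altering_classes = altering_classes)
}

#' Write a mutation catalog to TSV
#' @param mutations A [mutation_catalog()].
#' @param path Output path.
#' @export
write_mutations <- function(mutations, path) {
  readr::write_tsv(mutations[, c("sample", "gene", "mutation_class")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, fields name, description, then member
#' genes, tab-separated. Genes are deduplicated within each set.
#'
#' @inheritParams read_matrix
#' @return Named list of character vectors (a pathway collection).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    sets[[fields[[1]]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a two-column edge/pair TSV
#' @inheritParams read_matrix
#' @param cols Expected column names.
#' @return A tibble with the requested columns.
#' @export
read_pairs <- function(path, cols = c("gene_a", "gene_b")) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(cols %in% names(tbl))) {
    abort(paste0("expected header: ", paste(cols, collapse = "\t")))
  }
  tibble::as_tibble(tbl[, cols])
}

#' Read an ATC code catalog from TSV
#'
#' Columns `drug`, `atc_code`; codes must be non-empty uppercase
#' alphanumeric strings.
#'
#' @inheritParams read_matrix
#' @return Named list mapping drug to a character vector of ATC codes.
#' @export
read_atc <- function(path) {
  tbl <- read_pairs(path, cols = c("drug", "atc_code"))
  bad <- !grepl("^[A-Z0-9]+$", tbl$atc_code)
  if (any(bad)) {
    abort(paste0("invalid ATC code: ", tbl$atc_code[which(bad)[1]]))
  }
  split(tbl$atc_code, tbl$drug)
}

# Columns serialized for interaction and drug-interaction records.
.result_list_cols <- c("per_dataset_p", "support")

#' Write interaction records with a metadata sidecar
#'
#' Writes a flat TSV (list-columns such as per-screen p-values are encoded
#' as `name:value;name:value` strings) plus a JSON sidecar
#' (`<path>.meta.json`) holding run metadata. [read_results()] reproduces
#' the records exactly.
#'
#' @param records Tibble of interaction or drug-interaction records.
#' @param path Output TSV path.
#' @param metadata Named list (seed, thresholds, dataset names, ...).
#' @export
write_results <- function(records, path, metadata = list()) {
  tbl <- tibble::as_tibble(records)
  for (col in intersect(.result_list_cols, names(tbl))) {
    tbl[[col]] <- vapply(tbl[[col]], encode_named_list, character(1))
  }
  num_cols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  for (col in num_cols) {
    tbl[[col]] <- format_full(tbl[[col]])
  }
  readr::write_tsv(tbl, path, na = "", progress = FALSE)
  meta <- c(metadata, list(columns = names(tbl), n_records = nrow(records)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE, trim = TRUE)
  }, character(1))
  out
}

encode_named_list <- function(x) {
  if (is.null(x) || length(x) == 0) return("")
  if (is.numeric(x)) {
    paste(sprintf("%s:%s", names(x), format_full(x)), collapse = ";")
  } else {
    paste(as.character(x), collapse = ";")
  }
}

decode_named_numeric <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(vapply(kv, function(p) as.numeric(p[[2]]), numeric(1)),
           vapply(kv, `[[`, character(1), 1))
}

decode_chr_set <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Read interaction records written by [write_results()]
#'
#' @param path TSV path (the `.meta.json` sidecar must sit next to it).
#' @return Tibble of records with list-columns restored; the metadata is
#'   attached as attribute `"metadata"`.
#' @export
read_results <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tbl) == 0) {
    tbl <- tibble::as_tibble(setNames(rep(list(character(0)), length(meta$columns)),
                                      meta$columns))
  }
  for (col in names(tbl)) {
    if (col %in% "per_dataset_p") {
      tbl[[col]] <- lapply(tbl[[col]], decode_named_numeric)
    } else if (col %in% "support") {
      tbl[[col]] <- lapply(tbl[[col]], decode_chr_set)
    } else {
      chr <- tbl[[col]]
      suppressWarnings(num <- as.numeric(chr))
      # numeric column iff every non-missing cell parses as a number
      if (any(!is.na(chr)) && all(is.na(chr) | !is.na(num))) {
        tbl[[col]] <- num
      } else if (any(!is.na(chr)) && all(chr %in% c("TRUE", "FALSE", NA_character_))) {
        tbl[[col]] <- as.logical(chr)
      }
    }
  }
  attr(tbl, "metadata") <- meta
  tbl
}
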