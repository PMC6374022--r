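#' Binary individual-by-phecode phenotype matrix
#'
#' Light container for the sparse binary matrix `X` the topic model is fit
#' to: entry `X[i, j] = 1` iff individual `i` ever received a diagnosis code
#' mapping to phecode `j`.
#'
#' @param X Matrix coercible to a sparse 0/1 matrix.
#' @param individual_ids Unique row labels.
#' @param phecodes Unique column labels.
#' @return Object of class `phenotype_matrix` with fields `X` (dgCMatrix
#'   with dimnames), `individual_ids`, `phecodes`.
#' @export
phenotype_matrix <- function(X, individual_ids, phecodes) {
  X <- as_sparse_binary(X)
  if (nrow(X) != length(individual_ids) || ncol(X) != length(phecodes)) {
    stop_format("label lengths (%d, %d) do not match matrix dim (%d, %d)",
                length(individual_ids), length(phecodes), nrow(X), ncol(X))
  }
  if (anyDuplicated(individual_ids)) stop_format("duplicate individual ids")
  if (anyDuplicated(phecodes)) stop_format("duplicate phecode labels")
  vals <- unique(X@x)
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop_domain("phenotype matrix entries must be 0/1")
  }
  dimnames(X) <- list(individual_ids, phecodes)
  structure(
    list(X = X, individual_ids = as.character(individual_ids),
         phecodes = as.character(phecodes)),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("<phenotype_matrix> %d individuals x %d phecodes, density %.4f\n",
              nrow(x$X), ncol(x$X), Matrix::mean(x$X)))
  invisible(x)
}

#' @export
dim.phenotype_matrix <- function(x) dim(x$X)

#' Read an ICD-to-phecode mapping table
#'
#' Reads the standard published phecode map dialect: a CSV with at least the
#' columns `icd9` and `phecode`. An ICD code may map to several phecodes
#' (many-to-many maps are kept); exact duplicate rows are dropped.
#'
#' @param path CSV file path.
#' @return A tibble of class `phecode_map` with columns `icd9`, `phecode`,
#'   both character, whitespace-trimmed.
#' @export
read_phecode_map <- function(path) {
  if (!file.exists(path)) stop_format("phecode map file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  missing <- setdiff(c("icd9", "phecode"), names(df))
  if (length(missing)) {
    stop_format("phecode map lacks required column(s): %s",
                paste(missing, collapse = ", "))
  }
  map <- df |>
    mutate(icd9 = trimws(.data$icd9), phecode = trimws(.data$phecode)) |>
    filter(.data$icd9 != "", .data$phecode != "") |>
    distinct(.data$icd9, .data$phecode)
  class(map) <- c("phecode_map", class(map))
  map
}

#' Build the binary phenotype matrix from diagnosis records
#'
#' Maps each coded diagnosis to its phecode(s) and marks presence:
#' `X[i, j] = 1` iff individual `i` has at least one record mapping to
#' phecode `j`. Record multiplicity is deliberately discarded -- the analysis
#' works on presence/absence. Unmapped ICD codes are dropped (count
#' reported via a message); individuals whose records are all unmapped are
#' excluded, since an all-zero row carries no information for the
#' factorization and has no defined topic assignment.
#'
#' @param records Data frame with columns `individual_id` and `icd_code`
#'   (one row per coded diagnosis; duplicates allowed).
#' @param map A [read_phecode_map()] table, or any data frame with `icd9`
#'   and `phecode` columns.
#' @return A [phenotype_matrix]; columns ordered lexicographically by
#'   phecode, rows by first appearance of each retained individual.
#' @export
#' @examples
#' recs <- tibble::tibble(individual_id = c("a", "b", "b"),
#'                        icd_code = c("272.4", "272.4", "401.1"))
#' map <- tibble::tibble(icd9 = c("272.4", "401.1"),
#'                       phecode = c("272.1", "401.1"))
#' build_phenotype_matrix(recs, map)$X
build_phenotype_matrix <- function(records, map) {
  if (!all(c("individual_id", "icd_code") %in% names(records))) {
    stop_format("records need columns `individual_id` and `icd_code`")
  }
  if (nrow(records) == 0L) stop_domain("no diagnosis records supplied")
  recs <- tibble::as_tibble(records) |>
    mutate(individual_id = as.character(.data$individual_id),
           icd_code = trimws(as.character(.data$icd_code)))
  mapped <- recs |>
    left_join(tibble::as_tibble(map), by = c(icd_code = "icd9"),
              relationship = "many-to-many")
  n_unmapped <- sum(is.na(mapped$phecode))
  if (n_unmapped > 0) {
    message(sprintf("dropped %d record(s) with unmapped ICD codes", n_unmapped))
  }
  mapped <- filter(mapped, !is.na(.data$phecode))
  if (nrow(mapped) == 0L) {
    stop_domain("all records unmapped; phenotype matrix would be empty")
  }
  ids <- unique(recs$individual_id[recs$individual_id %in% mapped$individual_id])
  codes <- sort(unique(mapped$phecode))
  i <- match(mapped$individual_id, ids)
  j <- match(mapped$phecode, codes)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(ids), length(codes)))
  X@x[] <- 1  # collapse record multiplicity to presence
  phenotype_matrix(X, individual_ids = ids, phecodes = codes)
}

#' Write / read a phenotype matrix as MatrixMarket plus label TSVs
#'
#' Files written into `dir`: `X.mtx` (MatrixMarket coordinate format),
#' `individuals.tsv` and `phecodes.tsv` (single-column, with header).
#'
#' @param pm A [phenotype_matrix].
#' @param dir Directory (created if needed).
#' @return `write_phenotype_matrix`: `dir` invisibly.
#'   `read_phenotype_matrix`: the restored [phenotype_matrix].
#' @export
write_phenotype_matrix <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(pm$X, file.path(dir, "X.mtx"))
  readr::write_tsv(tibble(individual_id = pm$individual_ids),
                   file.path(dir, "individuals.tsv"))
  readr::write_tsv(tibble(phecode = pm$phecodes),
                   file.path(dir, "phecodes.tsv"))
  invisible(dir)
}

#' @rdname write_phenotype_matrix
#' @export
read_phenotype_matrix <- function(dir) {
  mtx <- file.path(dir, "X.mtx")
  if (!file.exists(mtx)) stop_format("no X.mtx under %s", dir)
  X <- Matrix::readMM(mtx)
  ids <- readr::read_tsv(file.path(dir, "individuals.tsv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  codes <- readr::read_tsv(file.path(dir, "phecodes.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(ids) == 0L || nrow(codes) == 0L) {
    stop_format("empty label file under %s", dir)
  }
  if (nrow(ids) != nrow(X) || nrow(codes) != ncol(X)) {
    stop_format("label counts (%d, %d) do not match matrix dim (%d, %d)",
                nrow(ids), nrow(codes), nrow(X), ncol(X))
  }
  phenotype_matrix(X, individual_ids = ids[[1]], phecodes = codes[[1]])
}
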