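#' Read a phenotype table from CSV
#'
#' Reads a per-individual phenotype CSV (differences in column naming across
#' common-garden and field tables are absorbed by \code{column_map}),
#' normalizes \code{"NA"} tokens to missing, recomputes
#' \code{total = linamarin + lotaustralin}, and checks any provided total
#' column against the recomputation (tolerance 1e-6).
#'
#' @param path CSV file with a header.
#' @param column_map named character vector mapping canonical names
#'   (\code{id}, \code{linamarin}, \code{lotaustralin}, \code{total},
#'   \code{brood}, \code{dam}, \code{sire}, \code{sex}, \code{generation},
#'   \code{treatment}, \code{population}) to the file's column names;
#'   identity by default.
#' @return Phenotype data frame with canonical column names.
#' @export
read_phenotype_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!(src %in% names(raw)))
        stop("mapped column not found in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  need <- c("id", "linamarin", "lotaustralin")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  raw$id <- as.character(raw$id)
  if (anyDuplicated(raw$id))
    stop("duplicate id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))
  for (col in c("linamarin", "lotaustralin")) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad) > 0)
      stop("negative ", col, " concentration at row(s): ",
           paste(bad, collapse = ", "))
  }
  total <- raw$linamarin + raw$lotaustralin
  if ("total" %in% names(raw)) {
    off <- which(!is.na(raw$total) & abs(raw$total - total) > 1e-6)
    if (length(off) > 0)
      stop("total column disagrees with linamarin + lotaustralin at row(s): ",
           paste(off, collapse = ", "))
  }
  raw$total <- total
  for (col in c("dam", "sire", "brood"))
    if (col %in% names(raw)) raw[[col]] <- as.character(raw[[col]])
  raw
}

#' Write a phenotype table to CSV
#'
#' @param phenos phenotype data frame.
#' @param path output path.
#' @return \code{path}, invisibly. Missing values are written as the token
#'   \code{"NA"}.
#' @export
write_phenotype_table <- function(phenos, path) {
  utils::write.csv(phenos, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pedigree table from CSV
#'
#' Reads a pedigree CSV (columns \code{id}, \code{dam}, \code{sire} and
#' optionally \code{sex}, \code{generation}; the token \code{"NA"} marks an
#' unknown parent), applying an optional column mapping, and validates it
#' with [validate_pedigree()].
#'
#' @param path CSV file with a header.
#' @param column_map named character vector mapping canonical column names
#'   to the file's names (as in [read_phenotype_table()]).
#' @return Validated, topologically ordered pedigree table.
#' @export
read_pedigree_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!(src %in% names(raw)))
        stop("mapped column not found in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  validate_pedigree(raw)
}

#' Write a pedigree table to CSV
#'
#' @param ped pedigree data frame.
#' @param path output path.
#' @return \code{path}, invisibly. Unknown parents are written as
#'   \code{"NA"}.
#' @export
write_pedigree_table <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a flat key-value simulation configuration
#'
#' Parses a plain-text file of \code{key = value} (or \code{key: value})
#' lines into a [sim_config()]. Numeric values are converted; vector values
#' are comma-separated; unknown keys are rejected. Lines starting with
#' \code{#} are comments.
#'
#' @param path text file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- lapply(lines, function(l) {
    parts <- strsplit(l, "[=:]", perl = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", l)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    list(key = key, val = val)
  })
  known <- names(formals(sim_config))
  args <- list()
  for (p in kv) {
    if (!(p$key %in% known)) stop("unknown config key: ", p$key)
    vals <- trimws(strsplit(p$val, ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    args[[p$key]] <- if (!any(is.na(num))) num else vals
  }
  do.call(sim_config, args)
}
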