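.ASSAY_COLUMNS <- c("donor_id", "sample_date", "mutation_id", "lineage",
                    "n_cells", "sex", "chrom_class", "nn", "mut_only",
                    "wt_only", "double_pos", "is_control")
.LINEAGE_LEVELS <- c("HSC", "MkP", "EP", "Myeloid", "B", "T", "proB", "other")

#' Read a ddPCR assay table
#'
#' Comma-separated by default (UTF-8, "." decimal); tab-separated via
#' `sep = "\t"`. Wells whose four quadrant counts total fewer than
#' `minDroplets` accepted events (default 8,000) are kept but flagged
#' `accepted = FALSE`. Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param sep field separator (`","` or `"\t"`).
#' @param minDroplets acceptance threshold on total droplets per well.
#' @return data.frame with the typed columns, plus `total_droplets` and
#'   `accepted`. Serial samples are ordered by donor, mutation and ISO date
#'   (ties keep file order).
#' @export
readAssayTable <- function(path, sep = ",", minDroplets = 8000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = c(sex = "character"))  # keep "F" a string
  missing <- setdiff(.ASSAY_COLUMNS, names(df))
  if (length(missing))
    stop("assay table lacks required column(s): ",
         paste(missing, collapse = ", "))

  cnt <- c("nn", "mut_only", "wt_only", "double_pos", "n_cells")
  for (col in cnt) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("column '", col, "' has negative or non-integer values at line(s) ",
           paste(bad + 1L, collapse = ", "))
    df[[col]] <- v
  }
  badLin <- which(!df$lineage %in% .LINEAGE_LEVELS)
  if (length(badLin))
    stop("unknown lineage at line(s) ", paste(badLin + 1L, collapse = ", "))
  badSex <- which(!df$sex %in% c("M", "F"))
  if (length(badSex))
    stop("sex must be M or F at line(s) ", paste(badSex + 1L, collapse = ", "))
  badChr <- which(!df$chrom_class %in% .CHROM_CLASSES)
  if (length(badChr))
    stop("unknown chrom_class at line(s) ", paste(badChr + 1L, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  if (!all(grepl("^\\d{4}-\\d{2}-\\d{2}$", df$sample_date)))
    stop("sample_date must be ISO-8601 (YYYY-MM-DD)")
  df$sample_date <- as.Date(df$sample_date)
  if (anyNA(df$sample_date)) stop("sample_date must be ISO-8601 (YYYY-MM-DD)")

  key <- df[, c("donor_id", "mutation_id", "lineage", "sample_date",
                "is_control")]
  if (anyDuplicated(key))
    stop("duplicate (donor, mutation, lineage, date, control) keys at line(s) ",
         paste(which(duplicated(key)) + 1L, collapse = ", "))

  df$total_droplets <- df$nn + df$mut_only + df$wt_only + df$double_pos
  df$accepted <- df$total_droplets >= minDroplets
  if (any(!df$accepted))
    message(sum(!df$accepted), " well(s) below ", minDroplets,
            " accepted droplets flagged rejected")
  df[order(df$donor_id, df$mutation_id, df$sample_date), , drop = FALSE]
}

#' One DropletAssay from an assay-table row
#'
#' @param row single row of a [readAssayTable()] data.frame.
#' @return A [DropletAssay-class].
#' @export
assayFromRow <- function(row) {
  stopifnot(nrow(row) == 1)
  DropletAssay(row$nn, row$mut_only, row$wt_only, row$double_pos,
               nCells = row$n_cells, chromClass = row$chrom_class,
               sex = row$sex)
}

#' Read a rooted mutation-count tree from newick
#'
#' Branch lengths carry integer mutation counts. Multi-tree files, unrooted
#' trees, negative counts and duplicated tip labels are rejected.
#'
#' @param path newick file path.
#' @param donorAge,gestationWeeks dating metadata (optional).
#' @return A [CladeTree-class].
#' @export
readCladeTree <- function(path, donorAge = NA_real_, gestationWeeks = 40) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("file contains ", length(tr),
                              " trees; exactly one is required")
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse a newick tree from ", path)
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch mutation counts")
  if (anyDuplicated(tr$tip.label)) stop("duplicated tip labels")
  cladeTree(tr, donorAge = donorAge, gestationWeeks = gestationWeeks)
}

#' Write a CladeTree to newick
#'
#' @param tree a [CladeTree-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCladeTree <- function(tree, path) {
  stopifnot(is(tree, "CladeTree"))
  ape::write.tree(treePhylo(tree), file = path)
  invisible(path)
}

#' Write a results report (JSON + TSV)
#'
#' Serialises a named result list to JSON with a config echo and a package
#' version stamp; any data.frame elements are additionally written as TSV
#' files next to the JSON (`<base>_<name>.tsv`). Output is byte-stable for a
#' fixed input: keys are emitted in a fixed order and no timestamps are
#' written.
#'
#' @param results named list of results (scalars, vectors, data.frames).
#' @param path output JSON path.
#' @param config optional [traceConfig()] to echo into the report.
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(results, path, config = NULL) {
  if (is.null(names(results)) && length(results))
    stop("results must be a named list")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  paths <- path
  base <- tools::file_path_sans_ext(path)
  isDf <- vapply(results, is.data.frame, TRUE)
  for (nm in names(results)[isDf]) {
    tsv <- paste0(base, "_", nm, ".tsv")
    write.table(results[[nm]], tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, tsv)
  }
  payload <- list(
    package = "cloneTrace",
    version = as.character(packageVersion("cloneTrace")),
    config = if (is.null(config)) NULL else unclass(config),
    results = results)
  payload <- payload[!vapply(payload, is.null, TRUE)]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(paths)
}
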