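#' Coordinate database of activation foci
#'
#' A `coord_db` holds one entry per experiment: a unique ID, an n x 3 matrix
#' of activation foci in MNI world millimetres, an optional subject count,
#' and (after [read_annotations()] or construction) a study-by-term
#' frequency matrix.
#'
#' @param experiments list of experiments, each a list with elements `id`
#'   (character), `foci` (n x 3 numeric matrix, mm), and optionally
#'   `n_subjects` (positive integer).
#' @param annotations optional numeric matrix (one row per experiment, in
#'   database order) of nonnegative term frequencies; column names form the
#'   vocabulary.
#' @return An object of class `coord_db`.
#' @export
coord_db <- function(experiments, annotations = NULL) {
  ids <- vapply(experiments, function(e) as.character(e$id), "")
  if (anyDuplicated(ids))
    stop("duplicated experiment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  experiments <- lapply(experiments, function(e) {
    foci <- e$foci
    if (is.null(foci)) foci <- matrix(numeric(0), 0, 3)
    foci <- matrix(as.numeric(foci), ncol = 3)
    if (!all(is.finite(foci))) stop("non-finite focus coordinates in ", e$id)
    list(id = as.character(e$id), foci = foci,
         n_subjects = if (!is.null(e$n_subjects)) as.integer(e$n_subjects))
  })
  db <- structure(list(experiments = experiments, ids = ids,
                       annotations = NULL, vocabulary = character(0)),
                  class = "coord_db")
  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations)
    stopifnot(nrow(annotations) == length(ids))
    if (any(annotations < 0)) stop("negative term frequencies")
    rownames(annotations) <- ids
    db$annotations <- annotations
    db$vocabulary <- colnames(annotations)
  }
  db
}

#' @export
print.coord_db <- function(x, ...) {
  nf <- vapply(x$experiments, function(e) nrow(e$foci), 0L)
  cat("Coordinate database:", length(x$ids), "experiments,",
      sum(nf), "foci (MNI mm)\n")
  if (length(x$vocabulary))
    cat("  annotated with", length(x$vocabulary), "terms\n")
  invisible(x)
}

#' Number of experiments in a database
#' @param db a [coord_db()].
#' @export
n_experiments <- function(db) length(db$ids)

#' Per-experiment focus counts
#' @param db a [coord_db()].
#' @export
focus_counts <- function(db) {
  stats::setNames(vapply(db$experiments, function(e) nrow(e$foci), 0L),
                  db$ids)
}

#' Read a Sleuth-style foci text file
#'
#' The dialect is the plain-text interchange format for coordinate-based
#' meta-analysis: a `// Reference=MNI` header, then blank-line-separated
#' study blocks.  Each block starts with one or more `//` comment lines
#' (the first names the experiment; an optional `// Subjects=n` line gives
#' the sample size) followed by one whitespace-separated x y z millimetre
#' triplet per line.  Talairach-space files are rejected: no coordinate
#' conversion is attempted.
#'
#' @param path path to the foci file.
#' @return A [coord_db()] (without annotations).
#' @export
read_foci_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ref <- grep("^\\s*//\\s*Reference\\s*=", lines, value = TRUE)
  if (length(ref) == 0L) stop("no coordinate-space header (// Reference=...)")
  space <- trimws(sub("^\\s*//\\s*Reference\\s*=", "", ref[1]))
  if (!grepl("^MNI", space, ignore.case = TRUE))
    stop("unsupported coordinate space '", space, "'; only MNI is accepted")
  ref_line <- grep("^\\s*//\\s*Reference\\s*=", lines)[1]

  experiments <- list()
  cur_id <- NULL; cur_subj <- NULL; cur_foci <- list()
  flush <- function() {
    if (is.null(cur_id) && length(cur_foci) == 0L) return()
    if (is.null(cur_id)) stop("coordinate block without a study header")
    experiments[[length(experiments) + 1L]] <<- list(
      id = cur_id,
      foci = do.call(rbind, cur_foci),
      n_subjects = cur_subj)
    cur_id <<- NULL; cur_subj <<- NULL; cur_foci <<- list()
  }
  for (ln in seq_along(lines)) {
    if (ln == ref_line) next
    line <- trimws(lines[ln])
    if (line == "") { flush(); next }
    if (startsWith(line, "//")) {
      body <- trimws(sub("^//", "", line))
      if (grepl("^Subjects\\s*=", body, ignore.case = TRUE)) {
        cur_subj <- as.integer(sub("^Subjects\\s*=\\s*", "", body,
                                   ignore.case = TRUE))
      } else if (is.null(cur_id)) {
        cur_id <- body
      }
      next
    }
    parts <- strsplit(line, "[\\s,;]+", perl = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3L || any(is.na(vals)))
      stop("non-numeric coordinate line at line ", ln, ": '", line, "'")
    if (is.null(cur_id)) stop("coordinates before any study header at line ", ln)
    cur_foci[[length(cur_foci) + 1L]] <- vals
  }
  flush()
  if (length(experiments) == 0L) stop("no experiments found in ", path)
  coord_db(experiments)
}

#' Write a database to a Sleuth-style foci text file
#'
#' @param db a [coord_db()].
#' @param path output path.
#' @param digits coordinate precision (decimal places), default 6.
#' @export
write_foci_file <- function(db, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("// Reference=MNI", con)
  writeLines("", con)
  for (e in db$experiments) {
    writeLines(paste0("// ", e$id), con)
    if (!is.null(e$n_subjects))
      writeLines(paste0("// Subjects=", e$n_subjects), con)
    if (nrow(e$foci) > 0L) {
      coords <- formatC(e$foci, format = "f", digits = digits)
      writeLines(apply(coords, 1, paste, collapse = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Attach a study-by-term annotation table to a database
#'
#' Reads a tab-separated table whose first column holds experiment IDs and
#' whose remaining (numeric, nonnegative) columns hold term frequencies.
#' The column names become the database vocabulary.  IDs absent from the
#' database are reported with a warning; database experiments absent from
#' the table receive all-zero frequencies.
#'
#' @param path path to the TSV annotation table (UTF-8, header row).
#' @param db a [coord_db()].
#' @return The database with `annotations` and `vocabulary` filled in.
#' @export
read_annotations <- function(path, db) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation table needs an id column plus terms")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicated experiment ids in annotations: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  freqs <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(freqs)) stop("term frequency columns must be numeric")
  if (any(freqs < 0)) stop("negative term frequencies")
  unknown <- setdiff(ids, db$ids)
  if (length(unknown) > 0L)
    warning(length(unknown), " annotated id(s) absent from the database: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  never <- colnames(freqs)[colSums(freqs) == 0]
  if (length(never) > 0L)
    warning("term(s) never present in any study: ",
            paste(never, collapse = ", "))
  out <- matrix(0, nrow = length(db$ids), ncol = ncol(freqs),
                dimnames = list(db$ids, colnames(freqs)))
  keep <- ids %in% db$ids
  out[ids[keep], ] <- freqs[keep, , drop = FALSE]
  db$annotations <- out
  db$vocabulary <- colnames(out)
  db
}

#' Write a database's annotation table as TSV
#' @param db an annotated [coord_db()].
#' @param path output path.
#' @export
write_annotations <- function(db, path) {
  if (is.null(db$annotations)) stop("database has no annotations")
  tab <- data.frame(id = db$ids, db$annotations, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
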