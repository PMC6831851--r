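# On-disk artifacts are all plain TSV: count matrices (one file per
# state x technique x replicate), GMT-like complex/annotation catalogs,
# edge lists and phosphosite tables. Readers reject structural errors
# rather than repairing them; writers emit deterministically sorted output.

new_fraction_experiment <- function(counts, state, technique, replicate) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts))) stop("counts matrix must have protein rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate protein identifiers")
  if (any(counts < 0)) stop("negative counts are not allowed")
  structure(list(state = as.character(state),
                 technique = as.character(technique),
                 replicate = as.character(replicate),
                 counts = counts),
            class = "fraction_experiment")
}

#' Construct a fractionation experiment from a count matrix
#'
#' @param counts Integer matrix of distinct-peptide counts, proteins in rows
#'   (rownames required), ordered fractions in columns.
#' @param state,technique,replicate Experiment labels.
#' @return A `fraction_experiment`.
#' @export
fraction_experiment <- function(counts, state, technique, replicate = 1L) {
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("F%03d", seq_len(ncol(counts)))
  }
  new_fraction_experiment(counts, state, technique, replicate)
}

#' @export
print.fraction_experiment <- function(x, ...) {
  cat(sprintf("CF-MS experiment: state=%s technique=%s replicate=%s\n",
              x$state, x$technique, x$replicate))
  cat(sprintf("  %d proteins x %d fractions, %d nonzero cells\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Read a fraction-by-protein peptide-count matrix
#'
#' Expects a TSV with a header row of fraction labels and a first column of
#' protein identifiers. Missing cells are read as 0; malformed numeric cells,
#' negative counts and duplicate protein rows are rejected with the offending
#' row/column named.
#'
#' @param path Path to the TSV file.
#' @param state,technique,replicate Labels attached to the experiment.
#' @return A `fraction_experiment`.
#' @export
read_experiment <- function(path, state, technique, replicate = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expected a protein column plus >= 1 fraction")
  proteins <- raw[[1]]
  dup <- proteins[duplicated(proteins)]
  if (length(dup)) stop("duplicate protein id: ", dup[1])
  mat <- matrix(0L, nrow(raw), ncol(raw) - 1,
                dimnames = list(proteins, colnames(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1)) {
    cell <- raw[[j + 1]]
    cell[is.na(cell) | cell == ""] <- "0"
    val <- suppressWarnings(as.numeric(cell))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                   proteins[bad], colnames(raw)[j + 1]))
    }
    if (any(val < 0)) {
      bad <- which(val < 0)[1]
      stop(sprintf("negative count at row '%s', column '%s'",
                   proteins[bad], colnames(raw)[j + 1]))
    }
    mat[, j] <- as.integer(round(val))
  }
  new_fraction_experiment(mat, state, technique, replicate)
}

#' Write a fractionation experiment as TSV
#'
#' First column `protein`, remaining columns the ordered fraction labels,
#' integer cells. [read_experiment()] on the result is an identity round trip.
#'
#' @param exp A `fraction_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(exp, path) {
  stopifnot(inherits(exp, "fraction_experiment"))
  df <- data.frame(protein = rownames(exp$counts), exp$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_complex_catalog <- function(complexes) {
  if (length(complexes) == 0) stop("catalog contains no complexes of size >= 2")
  if (is.null(names(complexes)) || anyDuplicated(names(complexes))) {
    stop("complex ids must be unique and named")
  }
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  if (any(vapply(complexes, length, integer(1)) < 2)) {
    stop("complex member sets must have size >= 2")
  }
  structure(list(complexes = complexes,
                 universe = sort(unique(unlist(complexes)))),
            class = "complex_catalog")
}

#' Construct a reference complex catalog
#'
#' @param complexes Named list of member sets (each of size >= 2).
#' @return A `complex_catalog` with the member lists and their union
#'   (`universe`).
#' @export
complex_catalog <- function(complexes) new_complex_catalog(complexes)

#' @export
print.complex_catalog <- function(x, ...) {
  sizes <- vapply(x$complexes, length, integer(1))
  cat(sprintf("Complex catalog: %d complexes (sizes %d-%d), %d proteins\n",
              length(x$complexes), min(sizes), max(sizes),
              length(x$universe)))
  invisible(x)
}

# shared GMT-like parser: id <tab> description <tab> member...
parse_gmt <- function(path, min_size, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty ", what, " file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate ", what, " id: ", dup[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  small <- vapply(sets, length, integer(1)) < min_size
  if (any(small)) {
    warning(sprintf("dropped %d %s entr%s with fewer than %d members",
                    sum(small), what, if (sum(small) == 1) "y" else "ies",
                    min_size))
    sets <- sets[!small]
  }
  sets
}

#' Read a reference complex catalog (GMT-like TSV)
#'
#' Each line: complex id, description, then tab-separated member ids.
#' Complexes with fewer than 2 members are dropped with a warning; duplicate
#' ids and empty files are errors.
#'
#' @param path Path to the TSV file.
#' @return A `complex_catalog`.
#' @export
read_complex_catalog <- function(path) {
  new_complex_catalog(parse_gmt(path, min_size = 2, what = "complex"))
}

#' Write a complex catalog (or any list of member sets) as GMT-like TSV
#'
#' @param complexes A `complex_catalog` or named list of member sets.
#' @param path Output path.
#' @param descriptions Optional character vector of per-complex descriptions.
#' @return `path`, invisibly.
#' @export
write_complex_catalog <- function(complexes, path, descriptions = NULL) {
  if (inherits(complexes, "complex_catalog")) complexes <- complexes$complexes
  if (is.null(descriptions)) descriptions <- rep("", length(complexes))
  ids <- names(complexes)
  lines <- vapply(seq_along(complexes), function(i) {
    paste(c(ids[i], descriptions[i], sort(complexes[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read annotation sets (term -> member lists, GMT-like TSV)
#'
#' Like [read_complex_catalog()] but singleton sets are allowed.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors.
#' @export
read_annotation_sets <- function(path) {
  parse_gmt(path, min_size = 1, what = "annotation")
}

#' Write a network edge table as TSV
#'
#' Pairs are canonicalized and sorted lexicographically; numeric columns are
#' serialized with 15 significant digits so that [read_network()] reproduces
#' scores exactly to at least 12 significant digits.
#'
#' @param edges Data frame with `protein_a`, `protein_b` and score columns
#'   (e.g. the edge table of a static network, or a differential edge table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)))
  if (nrow(edges) > 0) {
    cp <- canonical_pairs(edges$protein_a, edges$protein_b)
    edges$protein_a <- cp$protein_a
    edges$protein_b <- cp$protein_b
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  }
  out <- edges
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.15g", out[[cn]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with `protein_a`, `protein_b` and numeric score columns.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (cn in setdiff(names(df), c("protein_a", "protein_b"))) {
    if (cn %in% c("significant")) df[[cn]] <- as.logical(df[[cn]])
  }
  df
}

#' Write a phosphosite table as TSV
#'
#' Columns: protein, position, residue, ascore, one detection flag per
#' (state, replicate), known_site, plus any retention columns already present.
#'
#' @param records Phosphosite data frame (see [simulate_phosphosites()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phosphosites <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite table
#'
#' @param path Path to a TSV written by [write_phosphosites()].
#' @return Phosphosite data frame with logical detection columns.
#' @export
read_phosphosites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("protein", "position", "residue", "ascore", "known_site")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing phosphosite columns: ",
                            paste(missing, collapse = ", "))
  if (!all(df$residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y")
  }
  for (cn in grep("_rep[0-9]+$", names(df), value = TRUE)) {
    df[[cn]] <- as.logical(df[[cn]])
  }
  df$known_site <- as.logical(df$known_site)
  df
}
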