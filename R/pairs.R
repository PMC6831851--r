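# Canonical (unordered) protein-pair handling shared by all modules.
# Pairs are stored with protein_a < protein_b lexicographically; the
# separator below cannot occur in protein identifiers read from TSV.

PAIR_SEP <- "\r"

#' Canonicalize protein pairs
#'
#' Orders each pair so that `protein_a` sorts lexicographically before
#' `protein_b`. All pair-valued tables in cofracnet use this canonical order.
#'
#' @param a,b Character vectors of protein identifiers (recycled together).
#' @return A data frame with columns `protein_a` and `protein_b`.
#' @export
#' @examples
#' canonical_pairs(c("B", "A"), c("A", "C"))
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (any(a == b)) stop("self-pairs are not allowed")
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = PAIR_SEP)
}

#' Enumerate within-complex protein pairs
#'
#' Expands a list of complex member sets into the unique set of canonical
#' co-complex pairs (the positive reference used for LLS fitting and for
#' evaluating planted simulations).
#'
#' @param complexes A list of character vectors (member sets), or a
#'   `complex_catalog`.
#' @return Data frame of canonical pairs, sorted lexicographically.
#' @export
cocomplex_pairs <- function(complexes) {
  if (inherits(complexes, "complex_catalog")) complexes <- complexes$complexes
  mats <- lapply(complexes, function(m) {
    m <- sort(unique(as.character(m)))
    if (length(m) < 2) return(NULL)
    t(combn(m, 2))
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, mats)
  df <- data.frame(protein_a = m[, 1], protein_b = m[, 2],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# deterministic non-cryptographic hash of a label, used to derive
# condition-level RNG streams that are shared across replicates
label_hash <- function(x) {
  ints <- utf8ToInt(x)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647L
  as.integer(h)
}
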