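# Alignment input and site-pattern compression.
#
# Alignments are stored as a plain character matrix (taxa x sites) of
# upper-case IUPAC nucleotide codes.  Likelihood computations run on the
# pattern-compressed form, where identical columns are merged and carry an
# integer multiplicity.

# IUPAC code -> 0/1 compatibility vector over (A, C, G, T).
# Gaps and '?'/'X'/'N' are fully unknown (all ones); partial ambiguity codes
# get ones for every compatible nucleotide.
.iupac_masks <- local({
  m <- list(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1),
    X = c(1, 1, 1, 1), O = c(1, 1, 1, 1)
  )
  do.call(rbind, m)
})

.new_msa <- function(labels, seq_strings) {
  labels <- trimws(labels)
  if (length(labels) < 2L)
    stop("alignment must contain at least two taxa", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate taxon labels in alignment: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  seq_strings <- toupper(gsub("[[:space:]]", "", seq_strings))
  lens <- nchar(seq_strings)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  if (lens[1] < 1L) stop("alignment has zero columns", call. = FALSE)
  mat <- do.call(rbind, strsplit(seq_strings, ""))
  rownames(mat) <- labels
  bad <- setdiff(unique(as.vector(mat)), rownames(.iupac_masks))
  if (length(bad))
    stop("unknown sequence characters: ", paste(bad, collapse = " "), call. = FALSE)
  structure(list(labels = labels, seq = mat), class = "nr_msa")
}

#' Read a DNA alignment from a FASTA file
#'
#' Sequences are upper-cased and validated: all sequences must have equal
#' length, labels must be unique, and only IUPAC nucleotide codes (plus
#' \code{-}, \code{?}, \code{N}) are accepted.
#'
#' @param path Path to a FASTA file.
#' @return An object of class \code{nr_msa}: a list with \code{labels} and a
#'   taxa-by-sites character matrix \code{seq}.
#' @seealso [read_phylip()], [read_msa()], [compress_patterns()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  # keep only the first whitespace-delimited token as the taxon name
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  if (length(seqs) != length(labels))
    stop("FASTA record without sequence data", call. = FALSE)
  .new_msa(labels, unname(seqs))
}

#' Read a DNA alignment from a PHYLIP file
#'
#' Accepts sequential PHYLIP with a \code{"ntax nchar"} header line, in both
#' the strict (10-character name field) and relaxed (whitespace-delimited
#' name) dialects; the dialect is auto-detected per record.  Sequences may
#' continue over several lines.
#'
#' @inheritParams read_fasta
#' @return An object of class \code{nr_msa}.
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: ", lines[1], call. = FALSE)
  ntax <- as.integer(hdr[1]); nchar_exp <- as.integer(hdr[2])
  body <- lines[-1]
  labels <- character(ntax); seqs <- character(ntax)
  i <- 1L
  for (k in seq_len(ntax)) {
    if (i > length(body))
      stop("PHYLIP header announces ", ntax, " taxa but body has fewer records",
           call. = FALSE)
    line <- body[i]; i <- i + 1L
    if (grepl("^\\S+\\s", line)) {            # relaxed: name, whitespace, seq
      labels[k] <- sub("\\s.*$", "", line)
      chunk <- sub("^\\S+\\s+", "", line)
    } else {                                   # strict: first 10 chars = name
      labels[k] <- trimws(substr(line, 1L, 10L))
      chunk <- substr(line, 11L, nchar(line))
    }
    chunk <- gsub("[[:space:]]", "", chunk)
    # sequence may continue on following lines until nchar_exp is reached
    while (nchar(chunk) < nchar_exp && i <= length(body)) {
      nxt <- gsub("[[:space:]]", "", body[i])
      chunk <- paste0(chunk, nxt); i <- i + 1L
    }
    if (nchar(chunk) > nchar_exp)
      stop("PHYLIP sequence length disagrees with header (expected ",
           nchar_exp, ", record '", labels[k], "' overruns)", call. = FALSE)
    seqs[k] <- chunk
  }
  if (i <= length(body))
    stop("PHYLIP body has more records than the header announces", call. = FALSE)
  if (any(nchar(seqs) != nchar_exp))
    stop("PHYLIP sequence length disagrees with header (expected ",
         nchar_exp, ")", call. = FALSE)
  .new_msa(labels, seqs)
}

#' Read an alignment, auto-detecting FASTA vs PHYLIP
#'
#' Files whose first non-blank character is \code{>} are parsed as FASTA,
#' otherwise as PHYLIP.
#'
#' @inheritParams read_fasta
#' @return An object of class \code{nr_msa}.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && startsWith(trimws(first[1]), ">")) read_fasta(path)
  else read_phylip(path)
}

#' Compress an alignment into weighted site patterns
#'
#' Identical alignment columns are merged; each retained pattern carries the
#' number of original columns it represents.  Pattern order is the order of
#' first occurrence, so compression is deterministic.  Likelihoods computed
#' on the compressed alignment (weights as per-pattern multipliers) equal
#' those on the raw alignment.
#'
#' @param msa An \code{nr_msa}.
#' @return An object of class \code{nr_pmsa}: \code{labels}, a taxa-by-pattern
#'   character matrix \code{patterns}, and integer \code{weights} summing to
#'   the original alignment length.
#' @export
compress_patterns <- function(msa) {
  stopifnot(inherits(msa, "nr_msa"))
  keys <- apply(msa$seq, 2L, paste, collapse = "")
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  weights <- tabulate(idx, nbins = sum(first))
  structure(list(labels = msa$labels,
                 patterns = msa$seq[, first, drop = FALSE],
                 weights = as.integer(weights)),
            class = "nr_pmsa")
}

.as_pmsa <- function(x) {
  if (inherits(x, "nr_pmsa")) return(x)
  if (inherits(x, "nr_msa")) return(compress_patterns(x))
  stop("expected an nr_msa or nr_pmsa object", call. = FALSE)
}

#' @export
print.nr_msa <- function(x, ...) {
  cat("DNA alignment:", length(x$labels), "taxa x", ncol(x$seq), "sites\n")
  invisible(x)
}

#' @export
print.nr_pmsa <- function(x, ...) {
  cat("Pattern-compressed DNA alignment:", length(x$labels), "taxa,",
      ncol(x$patterns), "patterns (", sum(x$weights), "sites )\n")
  invisible(x)
}

# Tip conditional-likelihood masks for one taxon: 4 x npatterns matrix.
.tip_clv <- function(chars) t(.iupac_masks[chars, , drop = FALSE])

#' Write an alignment to a FASTA file
#'
#' @param msa An \code{nr_msa}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "nr_msa"))
  seqs <- apply(msa$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", msa$labels, "\n", seqs), path)
  invisible(path)
}
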