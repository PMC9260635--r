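## Alignment container: integer-coded character matrix plus optional
## partition (locus) map. State codes are 1..K into `alphabet`; 0 marks
## gaps/ambiguities, which the likelihood treats as fully missing.

DNA_ALPHABET <- c("a", "c", "g", "t")

#' Build an alignment block from a character matrix
#'
#' @param x character matrix (taxa in rows, sites in columns) with taxon
#'   labels as rownames, or a named character vector of equal-length
#'   sequences.
#' @param alphabet state alphabet; characters outside it (gaps, ambiguity
#'   codes) are coded as missing. Case-insensitive for DNA.
#' @param partitions optional `data.frame(locus, start, end)` of 1-based
#'   inclusive site ranges; ranges must be disjoint and within bounds.
#' @return object of class `aln_block` with elements `states` (integer
#'   matrix, 0 = missing), `alphabet`, `partitions`.
#' @export
aln_block <- function(x, alphabet = DNA_ALPHABET, partitions = NULL) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("sequences must be named")
    if (length(unique(nchar(x))) != 1L) stop("sequences must have equal length")
    x <- do.call(rbind, lapply(strsplit(x, ""), identity))
    ## strsplit drops names through lapply; restore
  }
  if (is.null(rownames(x))) stop("alignment matrix must have taxon rownames")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels in alignment")
  states <- matrix(match(tolower(x), tolower(alphabet), nomatch = 0L),
                   nrow = nrow(x), dimnames = list(rownames(x), NULL))
  obj <- structure(list(states = states, alphabet = alphabet,
                        partitions = NULL), class = "aln_block")
  if (!is.null(partitions)) obj <- set_partitions(obj, partitions)
  obj
}

#' @export
print.aln_block <- function(x, ...) {
  cat("<alignment> ", nrow(x$states), " taxa x ", ncol(x$states),
      " sites, ", length(x$alphabet), "-state alphabet", sep = "")
  if (!is.null(x$partitions)) cat(", ", nrow(x$partitions), " loci", sep = "")
  cat("\n")
  invisible(x)
}

n_sites <- function(aln) ncol(aln$states)
n_taxa <- function(aln) nrow(aln$states)
aln_taxa <- function(aln) rownames(aln$states)

set_partitions <- function(aln, partitions) {
  stopifnot(all(c("locus", "start", "end") %in% names(partitions)))
  partitions <- partitions[order(partitions$start), , drop = FALSE]
  if (any(partitions$start < 1) || any(partitions$end > n_sites(aln)) ||
      any(partitions$start > partitions$end))
    stop("partition ranges out of bounds")
  if (nrow(partitions) > 1 &&
      any(partitions$start[-1] <= partitions$end[-nrow(partitions)]))
    stop("partition ranges overlap")
  aln$partitions <- partitions
  aln
}

#' Read a multiple sequence alignment (FASTA or relaxed PHYLIP)
#'
#' @param file path to the alignment.
#' @param format `"fasta"`, `"phylip"`, or `"auto"` (sniff: a leading `>`
#'   means FASTA).
#' @param alphabet state alphabet (DNA by default).
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "phylip"),
                           alphabet = DNA_ALPHABET) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  m <- ape::read.dna(file, format = if (format == "fasta") "fasta" else "sequential",
                     as.character = TRUE)
  if (!is.matrix(m)) stop("sequences are not aligned (unequal lengths)")
  if (is.null(rownames(m))) stop("alignment has no taxon labels")
  aln_block(m, alphabet = alphabet)
}

#' Write an alignment block as FASTA
#' @param aln an `aln_block`.
#' @param file output path.
#' @export
write_alignment <- function(aln, file) {
  chars <- matrix(c("-", aln$alphabet)[aln$states + 1L], nrow = nrow(aln$states))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(chars))) {
    writeLines(paste0(">", rownames(aln$states)[i]), con)
    writeLines(paste(chars[i, ], collapse = ""), con)
  }
  invisible(file)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `DNA, locus1 = 1-5000` (the leading datatype token is
#' ignored; comma-separated multi-ranges are supported).
#'
#' @param file path to the partition file.
#' @return `data.frame(locus, start, end)`, one row per contiguous range.
#' @export
read_partitions <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^[^,]+,\\s*([^=]+)=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse partition line: ", ln)
    locus <- trimws(m[2])
    for (rg in strsplit(m[3], ",", fixed = TRUE)[[1]]) {
      nums <- as.integer(strsplit(trimws(rg), "-", fixed = TRUE)[[1]])
      if (length(nums) == 1) nums <- c(nums, nums)
      out[[length(out) + 1]] <- data.frame(locus = locus, start = nums[1],
                                           end = nums[2])
    }
  }
  do.call(rbind, out)
}

#' Write a RAxML-style partition file
#' @param partitions `data.frame(locus, start, end)`.
#' @param file output path.
#' @param datatype leading datatype token, default `"DNA"`.
#' @export
write_partitions <- function(partitions, file, datatype = "DNA") {
  writeLines(sprintf("%s, %s = %d-%d", datatype, partitions$locus,
                     partitions$start, partitions$end), file)
  invisible(file)
}

## Site-pattern compression: unique columns + multiplicities. Taxon order
## follows `taxa` so the result can be fed straight to the pruning kernel.
compress_patterns <- function(aln, taxa = aln_taxa(aln)) {
  missing_taxa <- setdiff(taxa, aln_taxa(aln))
  if (length(missing_taxa))
    stop("alignment lacks taxa: ", paste(missing_taxa, collapse = ", "))
  m <- aln$states[taxa, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = ".")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  w <- tabulate(idx, nbins = sum(first))
  list(patterns = m[, first, drop = FALSE], weights = w, site_index = idx)
}
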