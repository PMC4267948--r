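# Alignment container and I/O.
#
# An alignment is a character matrix of uppercase IUPAC symbols, one row per
# taxon (rownames = taxon names), one column per site.

#' IUPAC nucleotide alphabet accepted in alignments
#'
#' The four resolved bases, the eleven ambiguity codes, and the missing-data
#' symbols `-` and `?` (both read as "any base"). `U` is accepted on input
#' and mapped to `T`.
#'
#' @export
iupac_alphabet <- function() {
  c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
    "B", "D", "H", "V", "N", "-", "?")
}

#' Construct and validate an alignment
#'
#' @param sequences Either a named character vector of equal-length sequence
#'   strings, or a character matrix of single symbols with taxon rownames.
#' @return An object of class `phyloerr_alignment`: a character matrix of
#'   uppercase symbols, rows named by taxon.
#' @examples
#' aln <- alignment(c(tax1 = "ACGT", tax2 = "ACGA"))
#' n_sites(aln)
#' @export
alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
      stop("sequences must be named by taxon")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      bad <- names(sequences)[which(lens != lens[1L])[1L]]
      stop("sequences have unequal lengths (taxon '", bad, "')")
    }
    m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (is.null(rownames(m)) || any(!nzchar(rownames(m)))) {
    stop("alignment rows must be named by taxon")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate taxon name: '",
         rownames(m)[anyDuplicated(rownames(m))], "'")
  }
  if (ncol(m) < 1L) stop("alignment must have at least one site")
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  bad <- which(!(m %in% iupac_alphabet()))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop("illegal symbol '", m[bad[1L]], "' for taxon '", rownames(m)[i],
         "' at column ", j)
  }
  structure(m, class = c("phyloerr_alignment", "matrix", "array"))
}

#' @export
print.phyloerr_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x), "taxa,", ncol(x), "sites\n")
  show <- min(ncol(x), 60L)
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  }
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An alignment.
#' @export
n_sites <- function(aln) ncol(aln)

#' Taxon names of an alignment
#' @param aln An alignment.
#' @export
taxa <- function(aln) rownames(aln)

as_alignment <- function(x) {
  if (inherits(x, "phyloerr_alignment")) x else alignment(x)
}

#' Read a nucleotide alignment from file
#'
#' PHYLIP files (sequential or interleaved, relaxed whitespace-delimited
#' names) are auto-detected; FASTA is read via \pkg{ape}. Symbols are
#' uppercased and `U` mapped to `T` on read.
#'
#' @param path Path to the alignment file.
#' @param format `"phylip"` or `"fasta"`.
#' @return A validated alignment.
#' @export
read_alignment <- function(path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    seqs <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                          as.matrix = FALSE)
    if (is.matrix(seqs)) {
      return(alignment(seqs))
    }
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged FASTA: taxon '", names(seqs)[which(lens != lens[1])[1]],
           "' has ", lens[which(lens != lens[1])[1]], " sites, expected ",
           lens[1])
    }
    m <- do.call(rbind, seqs)
    rownames(m) <- names(seqs)
    return(alignment(m))
  }
  read_phylip(path)
}

# PHYLIP reader: accepts sequential and interleaved layouts, names
# whitespace-delimited, sequences possibly wrapped/blocked with internal
# whitespace. Tries sequential first, then interleaved.
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]) || hdr[1L] < 1L || hdr[2L] < 1L) {
    stop("malformed PHYLIP header at line 1 of ", path)
  }
  ntax <- hdr[1L]; nsite <- hdr[2L]
  body <- lines[-1L]
  body <- body[trimws(body) != ""]
  for (layout in c("sequential", "interleaved")) {
    res <- try(parse_phylip_body(body, ntax, nsite, layout), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("could not parse PHYLIP body of ", path, " (", ntax, " taxa, ",
       nsite, " sites) as sequential or interleaved: ",
       attr(res, "condition")$message)
}

parse_phylip_body <- function(body, ntax, nsite, layout) {
  strip <- function(x) gsub("\\s+", "", x)
  nm <- character(ntax)
  sq <- character(ntax)
  if (layout == "sequential") {
    i <- 1L
    for (k in seq_len(ntax)) {
      if (i > length(body)) stop("unexpected end of file at taxon ", k)
      tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
      nm[k] <- tok[1L]
      sq[k] <- paste(tok[-1L], collapse = "")
      i <- i + 1L
      while (nchar(sq[k]) < nsite) {
        if (i > length(body)) stop("sequence for taxon ", k, " is too short")
        sq[k] <- paste0(sq[k], strip(body[i]))
        i <- i + 1L
      }
    }
    if (i <= length(body)) stop("trailing lines after last taxon")
  } else {
    if (length(body) %% ntax != 0L) stop("line count not a multiple of ntax")
    for (k in seq_len(ntax)) {
      tok <- strsplit(trimws(body[k]), "\\s+")[[1L]]
      nm[k] <- tok[1L]
      sq[k] <- paste(tok[-1L], collapse = "")
    }
    extra <- body[-seq_len(ntax)]
    for (i in seq_along(extra)) {
      k <- ((i - 1L) %% ntax) + 1L
      sq[k] <- paste0(sq[k], strip(extra[i]))
    }
  }
  if (any(nchar(sq) != nsite)) {
    k <- which(nchar(sq) != nsite)[1L]
    stop("taxon '", nm[k], "' has ", nchar(sq[k]), " sites, header says ",
         nsite)
  }
  names(sq) <- nm
  alignment(sq)
}

#' Write an alignment to file
#'
#' PHYLIP output is sequential with whitespace-delimited (relaxed) names.
#'
#' @param aln An alignment.
#' @param path Output path.
#' @param format `"phylip"` or `"fasta"`.
#' @export
write_alignment <- function(aln, path, format = c("phylip", "fasta")) {
  aln <- as_alignment(aln)
  format <- match.arg(format)
  seqs <- apply(aln, 1L, paste, collapse = "")
  if (format == "phylip") {
    out <- c(paste(nrow(aln), ncol(aln)),
             paste(names(seqs), seqs))
  } else {
    out <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Compress alignment columns into distinct site patterns
#'
#' @param aln An alignment.
#' @return A `site_patterns` object: list with `taxa`, `patterns` (character
#'   matrix, one column per distinct site pattern, first-occurrence order),
#'   `weights` (integer multiplicities) and `n_sites`.
#' @export
compress_patterns <- function(aln) {
  aln <- as_alignment(aln)
  key <- apply(aln, 2L, paste, collapse = "")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  structure(
    list(taxa = rownames(aln),
         patterns = unclass(aln)[, first, drop = FALSE],
         weights = as.integer(tabulate(idx, nbins = sum(first))),
         n_sites = ncol(aln)),
    class = "site_patterns")
}

#' @export
print.site_patterns <- function(x, ...) {
  cat("Site patterns:", length(x$weights), "distinct over", x$n_sites,
      "sites,", length(x$taxa), "taxa\n")
  invisible(x)
}

as_site_patterns <- function(x) {
  if (inherits(x, "site_patterns")) x else compress_patterns(x)
}

#' Segregating sites per kilobase
#'
#' A site is segregating iff at least two distinct resolved bases
#' (`A`,`C`,`G`,`T`) occur in its column; ambiguity codes, gaps and missing
#' data never count toward polymorphism.
#'
#' @param aln An alignment.
#' @return `1000 * (number of segregating sites) / n_sites`.
#' @export
snp_density <- function(aln) {
  aln <- as_alignment(aln)
  pres <- vapply(c("A", "C", "G", "T"),
                 function(b) colSums(aln == b) > 0L,
                 logical(ncol(aln)))
  ndistinct <- rowSums(matrix(pres, ncol = 4L))
  1000 * sum(ndistinct >= 2L) / ncol(aln)
}
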