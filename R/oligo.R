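#' Oligonucleotide sequence
#'
#' A named DNA or RNA sequence written 5'->3' with an orientation
#' relative to the target transcript and optional 1-based inclusive
#' target coordinates on a reference sequence.
#'
#' @param name Sequence label.
#' @param bases IUPAC bases, `acgt` (DNA) or `acgu` (RNA); case
#'   insensitive, stored lowercase.
#' @param orientation "sense" or "antisense".
#' @param target_span Optional length-2 integer vector of 1-based
#'   inclusive coordinates on the reference (order-free; stored sorted).
#'   A span whose width differs from the sequence length is kept but
#'   flagged (`span_mismatch`), so printed annotation ambiguities are
#'   surfaced rather than silently corrected.
#' @param reference Reference accession the span refers to.
#' @param alphabet "DNA" or "RNA"; inferred from the bases when NULL
#'   (sequences containing neither t nor u default to DNA).
#' @return Object of class `oligo_seq`.
#' @export
oligo_seq <- function(name, bases, orientation = c("sense", "antisense"),
                      target_span = NULL, reference = "AF207748",
                      alphabet = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(bases), length(bases) == 1L, nchar(bases) >= 1)
  bases <- tolower(bases)
  chars <- strsplit(bases, "")[[1]]
  if (is.null(alphabet)) {
    alphabet <- if (all(chars %in% c("a", "c", "g", "t"))) "DNA"
                else if (all(chars %in% c("a", "c", "g", "u"))) "RNA"
                else stop("invalid or mixed alphabet in '", name, "'")
  } else {
    alphabet <- match.arg(alphabet, c("DNA", "RNA"))
    allowed <- if (alphabet == "DNA") c("a", "c", "g", "t")
               else c("a", "c", "g", "u")
    if (!all(chars %in% allowed)) {
      stop("invalid or mixed alphabet in '", name, "'")
    }
  }
  span_mismatch <- FALSE
  if (!is.null(target_span)) {
    stopifnot(length(target_span) == 2, all(target_span >= 1))
    target_span <- sort(as.integer(target_span))
    span_mismatch <- (target_span[2] - target_span[1] + 1L) != nchar(bases)
  }
  structure(
    list(name = name, bases = bases, alphabet = alphabet,
         orientation = orientation, target_span = target_span,
         reference = if (is.null(target_span)) NA_character_ else reference,
         span_mismatch = span_mismatch),
    class = "oligo_seq"
  )
}

#' @export
print.oligo_seq <- function(x, ...) {
  span <- if (is.null(x$target_span)) "" else {
    sprintf(" [%s %d-%d%s]", x$reference, x$target_span[1], x$target_span[2],
            if (x$span_mismatch) ", span/length mismatch" else "")
  }
  cat(sprintf("<oligo_seq> %s (%s, %s, %d nt)%s\n  5'-%s-3'\n",
              x$name, x$alphabet, x$orientation, nchar(x$bases), span,
              x$bases))
  invisible(x)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement preserving the alphabet (DNA stays
#' DNA, RNA stays RNA) and flipping the annotated orientation. An
#' involution: applying it twice returns the original sequence.
#'
#' @param seq An [oligo_seq()].
#' @return An [oligo_seq()].
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "oligo_seq"))
  rc <- if (seq$alphabet == "DNA") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq$bases)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq$bases)))
  }
  oligo_seq(paste0(seq$name, "_rc"), tolower(rc),
            orientation = if (seq$orientation == "sense") "antisense"
                          else "sense",
            target_span = seq$target_span,
            reference = if (is.na(seq$reference)) "AF207748" else seq$reference,
            alphabet = seq$alphabet)
}

#' Amplicon length from primer coordinates
#'
#' Inclusive span between a forward primer's 5' start and a reverse
#' primer's 3' end on the same reference:
#' `max(reverse span) - min(forward span) + 1`.
#'
#' @param forward,reverse [oligo_seq()]s carrying target spans on the
#'   same reference.
#' @return Amplicon length in bp.
#' @export
amplicon_length <- function(forward, reverse) {
  stopifnot(inherits(forward, "oligo_seq"), inherits(reverse, "oligo_seq"))
  if (is.null(forward$target_span) || is.null(reverse$target_span)) {
    stop("both primers need target coordinates")
  }
  if (!identical(forward$reference, reverse$reference)) {
    stop("primers annotated on different references")
  }
  lo <- min(forward$target_span)
  hi <- max(reverse$target_span)
  if (lo > hi) stop("forward primer must start 5' of the reverse primer end")
  hi - lo + 1L
}

normalize_dna <- function(seq) chartr("u", "t", seq$bases)

#' In-silico duplex call
#'
#' Computes the longest contiguous antiparallel Watson-Crick
#' complementary stretch between two oligos, exhaustively over all
#' relative offsets, and calls the pair bound when the run reaches
#' `min_run` nucleotides. U is treated as T for DNA/RNA pairing; G-U
#' wobble is not counted. This is the in-silico analogue of a gel-shift
#' hybridization assay. Symmetric in its arguments.
#'
#' @param a,b [oligo_seq()]s.
#' @param min_run Minimum complementary run (nt) for a bound call;
#'   the default 12 reproduces the gel-shift calls on the bundled probe
#'   panel.
#' @return List with `bound` (logical), `run` (nt), and the run's
#'   1-based start positions `a_start` (on a, 5'->3') and `b_start`
#'   (on b, 5'->3').
#' @export
duplex_call <- function(a, b, min_run = 12) {
  stopifnot(inherits(a, "oligo_seq"), inherits(b, "oligo_seq"))
  x <- strsplit(normalize_dna(a), "")[[1]]
  # antiparallel WC pairing of a against b == substring match of a
  # against the reverse complement of b
  brc <- chartr("acgt", "tgca",
                paste(rev(strsplit(normalize_dna(b), "")[[1]]), collapse = ""))
  y <- strsplit(brc, "")[[1]]
  n <- length(x)
  m <- length(y)
  best <- 0L
  best_ai <- 0L
  best_bi <- 0L
  for (off in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L + off)
    j0 <- i0 - off
    len <- min(n - i0, m - j0) + 1L
    if (len < 1L) next
    run <- 0L
    for (k in 0:(len - 1L)) {
      if (x[i0 + k] == y[j0 + k]) {
        run <- run + 1L
        if (run > best) {
          best <- run
          best_ai <- i0 + k - run + 1L
          best_bi <- j0 + k - run + 1L
        }
      } else {
        run <- 0L
      }
    }
  }
  # position on b in its own 5'->3' frame (best_bi indexes revcomp(b))
  b_start <- if (best > 0L) m - (best_bi + best - 1L) + 1L else NA_integer_
  list(bound = best >= min_run, run = best,
       a_start = if (best > 0L) best_ai else NA_integer_,
       b_start = b_start)
}

#' The printed probe and primer panel
#'
#' The eight oligos used for HDAC5 mRNA targeting and specificity
#' checks: the sense cDNA 20-mer at the miR-2861 binding site (hdac5),
#' its antisense probe (miD2861) with upstream primer USP1, a second
#' antisense probe (hdac5AS2) with upstream primer USP2, the miR-2861
#' passenger strand and precursor hairpin (RNA), and an antisense to the
#' precursor (mpremiR-2861a). Coordinates are 1-based inclusive on
#' GenBank AF207748. USP1 carries the annotated span 971-980, which is
#' shorter than the 20-mer; the mismatch is kept and flagged.
#'
#' @return Named list of [oligo_seq()]s.
#' @export
hdac5_oligo_panel <- function() {
  list(
    hdac5 = oligo_seq("hdac5", "aggctgagaggcaggccctt", "sense",
                      c(1169, 1188)),
    miD2861 = oligo_seq("miD2861", "aagggcctgcctctcagcct", "antisense",
                        c(1169, 1188)),
    USP1 = oligo_seq("USP1", "acggctttactggctcagtc", "sense",
                     c(971, 980)),
    hdac5AS2 = oligo_seq("hdac5AS2", "atctcattccacaccgtgtc", "antisense",
                         c(2341, 2360)),
    USP2 = oligo_seq("USP2", "tcaaggatgaggatggcgag", "sense",
                     c(1781, 1800)),
    passenger = oligo_seq("passenger", "cuccggcucccccuggccucccgg", "sense"),
    premiR2861 = oligo_seq("premiR2861",
                           "gaacuacaagucccagggggccuggcggcgggcggag", "sense"),
    mpremiR2861a = oligo_seq("mpremiR2861a", "ccctgggacttgtagttc",
                             "antisense")
  )
}

#' Read / write oligo FASTA
#'
#' FASTA with metadata encoded in the header:
#' `>name orientation=sense span=971-980 reference=AF207748`.
#'
#' @param path File path.
#' @param oligos Named list of [oligo_seq()]s (for writing).
#' @return Reading returns a named list of [oligo_seq()]s; writing
#'   returns `path` invisibly.
#' @export
read_oligo_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    hdr <- names(set)[i]
    parts <- strsplit(hdr, "\\s+")[[1]]
    nm <- parts[1]
    kv <- parts[-1]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA
    }
    ori <- get_field("orientation")
    span <- get_field("span")
    refn <- get_field("reference")
    span_v <- if (!is.na(span)) as.integer(strsplit(span, "-")[[1]]) else NULL
    out[[nm]] <- oligo_seq(nm, as.character(set[[i]]),
                           if (is.na(ori)) "sense" else ori,
                           target_span = span_v,
                           reference = if (is.na(refn)) "AF207748" else refn)
  }
  out
}

#' @rdname read_oligo_fasta
#' @export
write_oligo_fasta <- function(oligos, path) {
  hdrs <- vapply(oligos, function(o) {
    h <- paste0(o$name, " orientation=", o$orientation)
    if (!is.null(o$target_span)) {
      h <- paste0(h, " span=", o$target_span[1], "-", o$target_span[2],
                  " reference=", o$reference)
    }
    h
  }, character(1))
  set <- Biostrings::BStringSet(vapply(oligos, `[[`, character(1), "bases"))
  names(set) <- hdrs
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
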