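#' Reverse complement of a DNA string
#'
#' IUPAC-aware reverse complement (N maps to N, ambiguity codes to their
#' complements).
#'
#' @param sequence DNA string (IUPAC alphabet).
#' @return The reverse complement, read 5' to 3'.
#' @examples
#' reverse_complement("GCATTACGGCA")   # "TGCCGTAATGC"
#' @export
reverse_complement <- function(sequence) {
  s <- .as_upper_chr(sequence)[1L]
  if (nchar(s) == 0L) return("")
  .check_dna(s)
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Expand a DNA fragment into its six connected triplet-code sequences
#'
#' Reads the fragment as non-overlapping triplets in the three forward
#' frames, then in the three frames of the reverse complement, and connects
#' the six frames into one triplet-code sequence (frames 1-6 in order).
#' Only one of the six frames can be the true coding frame of a fragment,
#' but all six are kept so no coding information is lost on unannotated
#' fragments.
#'
#' @param sequence DNA string of length >= 3.
#' @return An object of class `triplet_code_sequence`: list with `frames`
#'   (list of 6 character vectors of triplets), `connected` (their
#'   concatenation in order), and `length` (fragment length in bp).
#' @examples
#' x <- six_frame_triplets("GCATTACGGCA")
#' x$frames[[1]]   # "GCA" "TTA" "CGG"
#' @export
six_frame_triplets <- function(sequence) {
  s <- .as_upper_chr(sequence)[1L]
  if (nchar(s) < 3L) stop("sequence must be at least 3 bp for triplet expansion")
  .check_dna(s)
  rc <- reverse_complement(s)
  frame_of <- function(seq, off) {
    n <- (nchar(seq) - off) %/% 3L
    if (n < 1L) return(character(0))
    substring(seq, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
  }
  frames <- c(lapply(0:2, function(o) frame_of(s, o)),
              lapply(0:2, function(o) frame_of(rc, o)))
  structure(
    list(frames = frames,
         connected = unlist(frames, use.names = FALSE),
         length = nchar(s)),
    class = "triplet_code_sequence"
  )
}

# all 64 triplets in lexicographic order (A < C < G < T): AAA -> 1, AAC -> 2,
# ..., TTT -> 64; this is the unique order consistent with the one-hot codes
# of AAA (bit 1) and AAC (bit 2)
ALL_TRIPLETS <- {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), times = 4L),
         rep(b, times = 16L))
}

#' One-hot encode a triplet-code sequence
#'
#' Each triplet becomes a 64-bit row with a single 1 at its lexicographic
#' index (AAA first, AAC second, ..., TTT last). Triplets containing an
#' ambiguous base become all-zero rows.
#'
#' @param triplets A `triplet_code_sequence` (the connected sequence is
#'   used) or a character vector of triplets.
#' @return A numeric `T x 64` matrix with row sums 1 (0 for ambiguous
#'   triplets); columns named by triplet.
#' @export
onehot_triplet_sequence <- function(triplets) {
  if (inherits(triplets, "triplet_code_sequence")) triplets <- triplets$connected
  idx <- match(toupper(triplets), ALL_TRIPLETS)
  m <- matrix(0, nrow = length(triplets), ncol = 64L,
              dimnames = list(NULL, ALL_TRIPLETS))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# 4-bit base codes: A=[0,0,0,1], C=[0,0,1,0], G=[0,1,0,0], T=[1,0,0,0]
BASE_CODES <- matrix(c(0, 0, 0, 1,
                       0, 0, 1, 0,
                       0, 1, 0, 0,
                       1, 0, 0, 0),
                     nrow = 4L, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))

#' One-hot encode the two connected base sequences of a fragment
#'
#' Encodes the positive strand followed by the complementary strand (the
#' reverse complement read 5' to 3') as one connected 2L x 4 matrix, using
#' the 4-bit codes A=[0,0,0,1], C=[0,0,1,0], G=[0,1,0,0], T=[1,0,0,0].
#' Ambiguous bases become zero rows.
#'
#' @param sequence DNA string of length >= 1.
#' @return A numeric `2L x 4` matrix.
#' @examples
#' encode_bases("A")   # rows for A then its complement T
#' @export
encode_bases <- function(sequence) {
  s <- .as_upper_chr(sequence)[1L]
  if (nchar(s) < 1L) stop("sequence must be non-empty")
  .check_dna(s)
  both <- paste0(s, reverse_complement(s))
  bases <- strsplit(both, "", fixed = TRUE)[[1L]]
  idx <- match(bases, rownames(BASE_CODES))
  m <- matrix(0, nrow = length(bases), ncol = 4L)
  ok <- !is.na(idx)
  m[ok, ] <- BASE_CODES[idx[ok], , drop = FALSE]
  m
}

# triplet rows of the connected six-frame sequence for a fragment of length L
.n_triplets <- function(L) 2L * sum((L - 0:2) %/% 3L)

#' Encode a fragment into the two fixed-shape network inputs
#'
#' Composes [six_frame_triplets()] + [onehot_triplet_sequence()] and
#' [encode_bases()], padding both matrices with zero rows to the fixed
#' shapes implied by `max_len` so fragments of different lengths can be
#' batched; the true (unpadded) row counts are recorded for masked average
#' pooling downstream.
#'
#' @param sequence DNA string with `min_len <= length <= max_len`.
#' @param max_len Maximum fragment length in bp (default 400, the training
#'   window).
#' @param min_len Minimum fragment length in bp (default 100).
#' @param source_id Identifier carried through to predictions.
#' @return An object of class `encoded_fragment`: list with `triplet_matrix`
#'   (`T_max x 64`), `base_matrix` (`2*max_len x 4`), `source_id`, `length`,
#'   `n_triplets` and `n_bases` (true row counts before padding).
#' @export
encode_fragment <- function(sequence, max_len = 400L, min_len = 100L,
                            source_id = "fragment") {
  s <- .as_upper_chr(sequence)[1L]
  L <- nchar(s)
  if (L < min_len) stop("sequence shorter than the configured minimum (",
                        min_len, " bp)")
  if (L > max_len) stop("sequence longer than max_len (", max_len, " bp)")
  tri <- onehot_triplet_sequence(six_frame_triplets(s))
  t_max <- .n_triplets(max_len)
  triplet_matrix <- rbind(tri, matrix(0, nrow = t_max - nrow(tri), ncol = 64L))
  colnames(triplet_matrix) <- ALL_TRIPLETS
  bm <- encode_bases(s)
  base_matrix <- rbind(bm, matrix(0, nrow = 2L * max_len - nrow(bm), ncol = 4L))
  structure(
    list(triplet_matrix = triplet_matrix, base_matrix = base_matrix,
         source_id = source_id, length = L,
         n_triplets = nrow(tri), n_bases = nrow(bm)),
    class = "encoded_fragment"
  )
}

## ---- integer-code encodings (internal fast path used by the network) ----

# per-character base index A=1 C=2 G=3 T=4, 0 for anything else
.BASE_LOOKUP <- local({
  v <- integer(256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
})

.base_codes_int <- function(s) .BASE_LOOKUP[utf8ToInt(s)]

# integer triplet codes (1..64 lexicographic, 0 = ambiguous) of one strand
# sequence at frame offset `off` (0..2)
.triplet_codes_frame <- function(b, off) {
  n <- (length(b) - off) %/% 3L
  if (n < 1L) return(integer(0))
  i1 <- off + 3L * seq_len(n) - 2L
  c1 <- b[i1]; c2 <- b[i1 + 1L]; c3 <- b[i1 + 2L]
  ok <- c1 > 0L & c2 > 0L & c3 > 0L
  out <- integer(n)
  out[ok] <- 16L * (c1[ok] - 1L) + 4L * (c2[ok] - 1L) + c3[ok]
  out
}

# encode a batch of sequences to fixed-width integer code matrices:
#   tcodes: B x n_triplets(max_len), connected six-frame triplet codes
#   bcodes: B x 2*max_len, positive strand then reverse complement
#   len:    true fragment lengths
# 0 entries are ambiguous bases/triplets or padding.
.encode_batch_codes <- function(sequences, max_len = 400L) {
  seqs <- toupper(as.character(sequences))
  B <- length(seqs)
  t_max <- .n_triplets(max_len)
  tcodes <- matrix(0L, B, t_max)
  bcodes <- matrix(0L, B, 2L * max_len)
  lens <- nchar(seqs)
  comp <- c(4L, 3L, 2L, 1L)
  for (i in seq_len(B)) {
    b <- .base_codes_int(seqs[i])
    rc <- rev(ifelse(b > 0L, comp[pmax(b, 1L)], 0L))
    tri <- c(.triplet_codes_frame(b, 0L), .triplet_codes_frame(b, 1L),
             .triplet_codes_frame(b, 2L),
             .triplet_codes_frame(rc, 0L), .triplet_codes_frame(rc, 1L),
             .triplet_codes_frame(rc, 2L))
    tcodes[i, seq_along(tri)] <- tri
    bcodes[i, seq_len(2L * lens[i])] <- c(b, rc)
  }
  list(tcodes = tcodes, bcodes = bcodes, len = lens)
}

# valid convolution-window weights for the triplet branch: windows of width
# `klen` that lie entirely inside one frame block (the six frames are
# distinct reading frames; windows straddling a frame junction would mix
# them, and masking them also makes the encoder exactly strand-symmetric).
# Returns a P-vector of weights summing to 1 (masked average pooling).
.triplet_window_weights <- function(L, max_len, klen = 6L) {
  t_max <- .n_triplets(max_len)
  P <- t_max - klen + 1L
  fl <- rep((L - 0:2) %/% 3L, 2L)          # six frame-block lengths
  starts <- cumsum(c(0L, fl[-6L]))         # 0-based block starts
  w <- numeric(P)
  for (f in seq_len(6L)) {
    if (fl[f] >= klen) {
      idx <- (starts[f] + 1L):(starts[f] + fl[f] - klen + 1L)
      w[idx] <- 1
    }
  }
  tot <- sum(w)
  if (tot == 0) stop("fragment too short for the convolution kernel")
  w / tot
}

# same for the base branch: two strand blocks of length L each
.base_window_weights <- function(L, max_len, klen = 6L) {
  P <- 2L * max_len - klen + 1L
  w <- numeric(P)
  if (L >= klen) {
    w[1:(L - klen + 1L)] <- 1
    w[(L + 1L):(2L * L - klen + 1L)] <- 1
  }
  tot <- sum(w)
  if (tot == 0) stop("fragment too short for the convolution kernel")
  w / tot
}

# weight matrices for a batch (rows: fragments); lengths repeat heavily so
# unique lengths are computed once
.batch_window_weights <- function(lens, max_len, klen = 6L) {
  uL <- sort(unique(lens))
  wt <- t(vapply(uL, .triplet_window_weights,
                 numeric(.n_triplets(max_len) - klen + 1L),
                 max_len = max_len, klen = klen))
  wb <- t(vapply(uL, .base_window_weights,
                 numeric(2L * max_len - klen + 1L),
                 max_len = max_len, klen = klen))
  i <- match(lens, uL)
  list(wt = wt[i, , drop = FALSE], wb = wb[i, , drop = FALSE])
}
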