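#' Build a genetic code with synonymous-codon categories
#'
#' Constructs the codon-to-amino-acid map for a translation table and derives
#' the amino-acid categories used by the IEA statistic: every amino acid with
#' more than one synonymous codon, plus a single "stop amino acid" category
#' that collapses all stop codons. Under the bacterial code (table 11) this
#' yields 19 categories: 18 degenerate amino acids and the stop category.
#'
#' @param table_id Integer NCBI translation table identifier. Defaults to 11
#'   (bacterial, archaeal and plant plastid code), the appropriate table for
#'   plasmid hosts.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over all 64 DNA
#'   triplets, stop codons mapped to `"*"`), `categories` (ordered character
#'   vector of category symbols), and `codons_by_category` (named list of the
#'   synonymous codons of each category).
#' @examples
#' code <- build_genetic_code(11)
#' length(code$categories)           # 19
#' code$codons_by_category[["L"]]    # the six leucine codons
#' @export
build_genetic_code <- function(table_id = 11L) {
  if (length(table_id) != 1L || is.na(table_id)) {
    stop("'table_id' must be a single translation table identifier")
  }
  tab <- tryCatch(
    Biostrings::getGeneticCode(as.character(table_id)),
    error = function(e) stop("unsupported translation table id: ", table_id,
                             call. = FALSE)
  )
  codon_to_aa <- as.character(tab)
  names(codon_to_aa) <- names(tab)
  stopifnot(length(codon_to_aa) == 64L)

  by_aa <- split(names(codon_to_aa), codon_to_aa)
  n_cod <- lengths(by_aa)
  # degenerate amino acids in alphabetical order, stop category ("*") last
  degenerate <- sort(setdiff(names(by_aa)[n_cod >= 2L], "*"))
  categories <- c(degenerate, "*")
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = codon_to_aa,
      categories = categories,
      codons_by_category = by_aa[categories]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> translation table %d: %d categories (%s)\n",
              x$table_id, length(x$categories),
              paste(x$categories, collapse = " ")))
  invisible(x)
}

IUPAC_DNA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")

.check_dna <- function(seqs, ids = NULL) {
  bad <- grepl(paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"), seqs)
  if (any(bad)) {
    offender <- if (!is.null(ids)) ids[which(bad)[1L]] else which(bad)[1L]
    stop("non-IUPAC characters in sequence record: ", offender, call. = FALSE)
  }
  invisible(TRUE)
}

.as_upper_chr <- function(x) {
  if (!is.character(x)) x <- as.character(x)  # DNAString(Set) etc.
  toupper(x)  # toupper keeps names; as.character would drop them
}

#' Tally synonymous codon usage over a set of coding sequences
#'
#' Counts every in-frame codon of every coding sequence into its amino-acid
#' category. Codons containing ambiguous bases are skipped; a trailing
#' partial codon is dropped with a warning.
#'
#' @param cds_list Character vector or `DNAStringSet` of coding sequences.
#' @param code A `genetic_code` from [build_genetic_code()].
#' @return An object of class `codon_counts`: list with `counts` (named list,
#'   one named integer vector of synonymous-codon counts per category) and
#'   `total_codons` (all counted codons, including single-codon amino acids).
#' @examples
#' code <- build_genetic_code()
#' count_synonymous_codons("ATGAAAAAGTAA", code)$counts[["K"]]
#' @export
count_synonymous_codons <- function(cds_list, code) {
  stopifnot(inherits(code, "genetic_code"))
  cds <- .as_upper_chr(cds_list)
  if (length(cds) == 0L) stop("empty coding-sequence list")
  ids <- names(cds)
  if (is.null(ids)) ids <- seq_along(cds)
  .check_dna(cds, ids)

  partial <- nchar(cds) %% 3L != 0L
  if (any(partial)) {
    warning(sum(partial), " sequence(s) had a trailing partial codon, dropped")
    cds[partial] <- substr(cds[partial], 1L, (nchar(cds[partial]) %/% 3L) * 3L)
  }
  cds <- cds[nchar(cds) > 0L]
  if (length(cds) == 0L) stop("no complete codons in coding-sequence list")

  codons <- unlist(lapply(cds, function(s) {
    n <- nchar(s) %/% 3L
    substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  }), use.names = FALSE)
  # ambiguous codons (any non-ACGT base) are skipped
  codons <- codons[!grepl("[^ACGT]", codons)]
  tab <- table(factor(codons, levels = names(code$codon_to_aa)))

  counts <- lapply(code$codons_by_category, function(cs) {
    v <- as.integer(tab[cs])
    names(v) <- cs
    v
  })
  structure(
    list(counts = counts, total_codons = length(codons)),
    class = "codon_counts"
  )
}

#' Information entropy of amino acid (IEA)
#'
#' Normalized Shannon entropy of the synonymous-codon frequency distribution
#' of one amino-acid category: `IEA = sum_j p_j * log_{n}(1/p_j)` with
#' `p_j = count_j / sum(counts)` and the convention `0 * log(1/0) = 0`.
#' The logarithm base equals the number of synonymous codons `n`, so the
#' statistic lies in `[0, 1]`: 1 for uniform usage, 0 when a single codon is
#' used exclusively.
#'
#' @param counts Non-negative integer (or numeric) vector of synonymous-codon
#'   counts for one category.
#' @param n_i Number of synonymous codons of the category (`>= 2`). Defaults
#'   to `length(counts)`.
#' @return A single value in `[0, 1]`, or `NA` if no codon was observed (an
#'   unobserved category is missing, never zero-entropy).
#' @examples
#' iea(c(1, 1, 1, 1))   # uniform usage -> 1
#' iea(c(5, 0))         # single-codon usage -> 0
#' @export
iea <- function(counts, n_i = length(counts)) {
  if (n_i < 2L) stop("'n_i' must be >= 2: a single-codon amino acid has no synonymous usage")
  if (length(counts) != n_i) stop("length(counts) must equal n_i")
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  val <- -sum(p * log(p)) / log(n_i)
  # guard against floating-point overshoot just past the analytic bounds
  min(max(val, 0), 1)
}

#' Per-genome IEA profile
#'
#' Computes one IEA value per amino-acid category for a genome. Coding
#' sequences are taken from the genome's CDS annotation when present;
#' otherwise open reading frames are predicted with [find_orfs()].
#'
#' @param genome A genome record (list with `genome_id`, `sequence`, optional
#'   `cds` annotation table and `label`, as returned by [read_genomes()] or
#'   [synth_genome()]), or a bare DNA string (ORF fallback).
#' @param code A `genetic_code`.
#' @param min_codons Minimum ORF length (in codons, stop included) for the
#'   ORF fallback.
#' @param source One of `"auto"` (CDS annotation when present, else ORFs),
#'   `"cds"`, or `"orf"` — which coding-sequence source feeds the codon tally.
#' @return An object of class `iea_profile`: list with `genome_id`, `iea`
#'   (named numeric over `code$categories`, `NA` for unobserved categories),
#'   `label`, `n_cds`, `total_codons`.
#' @export
iea_profile <- function(genome, code = build_genetic_code(),
                        min_codons = 60L, source = c("auto", "cds", "orf")) {
  source <- match.arg(source)
  if (is.character(genome) || inherits(genome, "DNAString")) {
    genome <- list(genome_id = "unnamed", sequence = .as_upper_chr(genome)[1L],
                   cds = NULL, label = NA_character_)
  }
  has_cds <- !is.null(genome$cds) && nrow(genome$cds) > 0L
  use_cds <- switch(source,
    auto = has_cds,
    cds = if (has_cds) TRUE else stop("genome has no CDS annotation"),
    orf = FALSE
  )
  cds_seqs <- if (use_cds) {
    cds_sequences(genome)
  } else {
    find_orfs(genome$sequence, min_codons = min_codons)
  }
  if (length(cds_seqs) == 0L) {
    stop("no usable coding sequences for genome ", genome$genome_id)
  }
  cc <- count_synonymous_codons(cds_seqs, code)
  vals <- vapply(code$categories, function(cat) {
    iea(cc$counts[[cat]], n_i = length(cc$counts[[cat]]))
  }, numeric(1))
  structure(
    list(genome_id = genome$genome_id %||% "unnamed",
         iea = vals,
         label = genome$label %||% NA_character_,
         n_cds = length(cds_seqs),
         total_codons = cc$total_codons),
    class = "iea_profile"
  )
}

#' @export
print.iea_profile <- function(x, ...) {
  cat(sprintf("<iea_profile> %s (%s): %d CDS, %d codons, mean IEA %.3f\n",
              x$genome_id, x$label, x$n_cds, x$total_codons,
              mean(x$iea, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ORF_STARTS <- c("ATG", "GTG", "TTG")

#' Find stop-closed open reading frames
#'
#' Scans all six reading frames for maximal stop-to-stop ORFs that begin at
#' ATG/GTG/TTG and end with a stop codon (included in the returned sequence).
#' Only stop-closed ORFs are reported; open-ended runs at sequence ends are
#' excluded to avoid frame-shift noise. Within a stop-to-stop segment the
#' earliest start is taken, so ORFs are non-nested per frame.
#'
#' @param sequence DNA string.
#' @param min_codons Minimum ORF length in codons, stop codon included
#'   (`>= 2`).
#' @param code A `genetic_code` supplying the stop codons.
#' @return Character vector of ORF nucleotide sequences (possibly empty).
#' @export
find_orfs <- function(sequence, min_codons = 60L, code = build_genetic_code()) {
  if (min_codons < 2L) stop("'min_codons' must be >= 2")
  s <- .as_upper_chr(sequence)[1L]
  .check_dna(s)
  stops <- code$codons_by_category[["*"]]
  orfs <- character(0)
  for (strand_seq in c(s, reverse_complement(s))) {
    L <- nchar(strand_seq)
    for (off in 0:2) {
      n <- (L - off) %/% 3L
      if (n < 1L) next
      cod <- substring(strand_seq, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
      is_stop <- cod %in% stops
      seg_start <- 1L
      for (k in which(is_stop)) {
        seg <- seg_start:k
        starts_in_seg <- seg[cod[seg] %in% ORF_STARTS]
        if (length(starts_in_seg) > 0L) {
          first <- starts_in_seg[1L]
          if (k - first + 1L >= min_codons) {
            orfs <- c(orfs, paste(cod[first:k], collapse = ""))
          }
        }
        seg_start <- k + 1L
      }
    }
  }
  orfs
}

#' Compare IEA profiles of two genome groups
#'
#' For each amino-acid category, reports the group means, the AUC of using
#' that single IEA value to separate the two groups (rank-based, mid-rank
#' ties; group `a` treated as the positive class), and the two-sided
#' Wilcoxon rank sum p-value. Missing values are excluded per category.
#'
#' @param profiles_a,profiles_b Lists of `iea_profile` objects (e.g.
#'   transmissible vs non-transmissible genomes).
#' @param code A `genetic_code` fixing category order.
#' @return A `data.frame` with one row per category: `category`, `n_codons`
#'   (number of synonymous codons of the category), `n_a`, `n_b` (profiles
#'   with an observed value), `mean_a`, `mean_b`, `auc`, `p_value`, `note`
#'   (flags a category unobserved in an entire group).
#' @export
compare_groups <- function(profiles_a, profiles_b, code = build_genetic_code()) {
  if (length(profiles_a) == 0L || length(profiles_b) == 0L) {
    stop("both groups must be non-empty")
  }
  get_mat <- function(ps) do.call(rbind, lapply(ps, function(p) p$iea[code$categories]))
  ma <- get_mat(profiles_a)
  mb <- get_mat(profiles_b)
  rows <- lapply(seq_along(code$categories), function(i) {
    a <- ma[, i][!is.na(ma[, i])]
    b <- mb[, i][!is.na(mb[, i])]
    note <- ""
    if (length(a) == 0L || length(b) == 0L) {
      note <- "category unobserved in an entire group"
      return(data.frame(category = code$categories[i],
                        n_codons = length(code$codons_by_category[[i]]),
                        n_a = length(a), n_b = length(b),
                        mean_a = if (length(a)) mean(a) else NA_real_,
                        mean_b = if (length(b)) mean(b) else NA_real_,
                        auc = NA_real_, p_value = NA_real_, note = note))
    }
    data.frame(category = code$categories[i],
               n_codons = length(code$codons_by_category[[i]]),
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               auc = auc(c(a, b), rep(c(1L, 0L), c(length(a), length(b)))),
               p_value = .ranksum_p(a, b), note = note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# two-sided Wilcoxon rank sum p-value: exact enumeration for small tie-free
# groups, normal approximation with tie correction otherwise
.ranksum_p <- function(a, b) {
  want_exact <- length(a) <= 25L && length(b) <= 25L &&
    !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = want_exact, correct = FALSE)$p.value
  )
}

#' Write a group-comparison table to TSV
#'
#' @param comparison Output of [compare_groups()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
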