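#' Read genome records from FASTA or GenBank flat files
#'
#' FASTA records yield genomes without CDS annotation (the IEA profiler then
#' falls back to ORF prediction); GenBank flat files yield the ORIGIN
#' sequence plus the CDS feature coordinates, including `join()` and
#' `complement()` locations. Labels and train/test splits can be attached
#' from a table.
#'
#' @param path Path to a FASTA (`>`-led) or GenBank (`LOCUS`-led) file.
#' @param format `"auto"` (detected from the first non-blank line),
#'   `"fasta"` or `"genbank"`.
#' @param labels Optional `data.frame` with columns `genome_id`, `label`
#'   and optionally `split`, joined onto the records.
#' @return List of genome records: `genome_id`, `sequence`, `cds`
#'   (data.frame or `NULL`), `label`, `split`.
#' @export
read_genomes <- function(path, format = c("auto", "fasta", "genbank"),
                         labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 50L)
    first <- first[nzchar(trimws(first))][1L]
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  genomes <- if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    lapply(seq_along(x), function(i) {
      list(genome_id = ids[i], sequence = as.character(x[[i]]), cds = NULL,
           label = NA_character_, split = NA_character_)
    })
  } else {
    .read_genbank(path)
  }
  if (!is.null(labels)) {
    m <- match(vapply(genomes, `[[`, character(1), "genome_id"),
               labels$genome_id)
    genomes <- lapply(seq_along(genomes), function(i) {
      g <- genomes[[i]]
      if (!is.na(m[i])) {
        g$label <- as.character(labels$label[m[i]])
        if (!is.null(labels$split)) g$split <- as.character(labels$split[m[i]])
      }
      g
    })
  }
  genomes
}

# Minimal GenBank flat-file parser: LOCUS id, CDS feature locations
# (join/complement/order, partial markers stripped), ORIGIN sequence.
.read_genbank <- function(path) {
  lines <- readLines(path)
  rec_breaks <- grep("^//", lines)
  rec_starts <- c(1L, utils::head(rec_breaks, -1L) + 1L)
  Map(function(from, to) .parse_genbank_record(lines[from:to]),
      rec_starts, rec_breaks)
}

.parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  genome_id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]

  # ORIGIN block: strip coordinates and whitespace
  o <- grep("^ORIGIN", lines)
  seq_lines <- if (length(o)) lines[(o[1L] + 1L):length(lines)] else character(0)
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # CDS features: a feature key line at indent 5, location possibly wrapped
  feat_idx <- grep("^\\s{5}CDS\\s+\\S", lines)
  cds_rows <- list()
  for (k in seq_along(feat_idx)) {
    i <- feat_idx[k]
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[i]))
    j <- i + 1L
    while (j <= length(lines) && grepl("^\\s{21}[^/]", lines[j])) {
      loc <- paste0(loc, trimws(lines[j]))
      j <- j + 1L
    }
    parsed <- .parse_location(loc)
    if (!is.null(parsed)) {
      parsed$cds_id <- sprintf("%s_cds%03d", genome_id, k)
      cds_rows[[length(cds_rows) + 1L]] <- parsed
    }
  }
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else NULL
  list(genome_id = genome_id, sequence = sequence, cds = cds,
       label = NA_character_, split = NA_character_)
}

# parse a GenBank location string into rows (start, end, strand); the parts
# of a join are returned in order, a wrapping complement() flips the strand
.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)  # per-part complement
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- regmatches(parts, regexpr("[<>]?\\d+\\.\\.[<>]?\\d+", parts))
  if (length(spans) == 0L) return(NULL)
  nums <- lapply(strsplit(gsub("[<>]", "", spans), "..", fixed = TRUE),
                 as.integer)
  data.frame(start = vapply(nums, `[`, integer(1), 1L),
             end = vapply(nums, `[`, integer(1), 2L),
             strand = strand, stringsAsFactors = FALSE)
}

#' Compute IEA profiles for a set of genomes
#'
#' @param genomes List of genome records from [read_genomes()] or
#'   [synth_genome()].
#' @param code A `genetic_code`.
#' @param ... Passed to [iea_profile()] (e.g. `min_codons`, `source`).
#' @return List of `iea_profile` objects.
#' @export
iea_profiles <- function(genomes, code = build_genetic_code(), ...) {
  lapply(genomes, iea_profile, code = code, ...)
}

#' Write IEA profiles to a TSV (one row per genome, one column per category)
#'
#' @param profiles List of `iea_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  mat <- do.call(rbind, lapply(profiles, function(p) p$iea))
  df <- data.frame(genome_id = vapply(profiles, `[[`, character(1), "genome_id"),
                   label = vapply(profiles, `[[`, character(1), "label"),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read IEA profiles back from a TSV written by [write_profiles()]
#'
#' @param path TSV path.
#' @param code A `genetic_code` fixing category order.
#' @return List of `iea_profile` objects.
#' @export
read_profiles <- function(path, code = build_genetic_code()) {
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, code$categories])
    names(vals) <- code$categories
    structure(list(genome_id = as.character(df$genome_id[i]), iea = vals,
                   label = as.character(df$label[i]),
                   n_cds = NA_integer_, total_codons = NA_integer_),
              class = "iea_profile")
  })
}
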