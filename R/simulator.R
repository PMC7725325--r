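#' Sample host codon-usage tables of controlled divergence
#'
#' Generates `k` host codon-usage tables whose mutual divergence is tunable.
#' Each amino-acid category interpolates between the uniform distribution
#' over its synonymous codons (`divergence = 0`: all tables identical) and a
#' near-deterministic distribution concentrated on a table-specific
#' preferred codon (`divergence = 1`: mutually distinct preferred codons
#' wherever the category has enough codons). This emulates the premise that
#' distinct bacterial hosts impose distinct codon-usage signatures on the
#' plasmids they carry.
#'
#' @param k Number of host tables (`>= 1`).
#' @param divergence Real in `[0, 1]` controlling how far apart the tables
#'   are.
#' @param seed Integer seed (preferred-codon assignment is randomized per
#'   category).
#' @param gc_bias Intergenic G+C fraction in `(0, 1)` stored with each table.
#' @param code A `genetic_code`.
#' @return List of `k` objects of class `host_usage_table`: list with
#'   `probs` (named list, one probability vector over synonymous codons per
#'   category, plus the single-codon amino acids), `gc_bias`, `divergence`.
#' @export
sample_usage_tables <- function(k, divergence, seed = 1L, gc_bias = 0.5,
                                code = build_genetic_code()) {
  stopifnot(k >= 1L, divergence >= 0, divergence <= 1,
            gc_bias > 0, gc_bias < 1)
  eps <- 0.02  # residual mass off the preferred codon at full divergence
  by_aa <- split(names(code$codon_to_aa), code$codon_to_aa)
  withr::with_seed(as.integer(seed), {
    rot <- vapply(by_aa, function(cs) sample.int(length(cs), 1L) - 1L,
                  integer(1))
    lapply(seq_len(k), function(m) {
      probs <- lapply(seq_along(by_aa), function(ci) {
        cs <- by_aa[[ci]]
        n <- length(cs)
        if (n == 1L) {
          p <- 1
        } else {
          pref <- ((rot[ci] + m - 1L) %% n) + 1L
          peaked <- rep(eps / (n - 1L), n)
          peaked[pref] <- 1 - eps
          p <- (1 - divergence) / n + divergence * peaked
        }
        names(p) <- cs
        p
      })
      names(probs) <- names(by_aa)
      structure(list(probs = probs, gc_bias = gc_bias,
                     divergence = divergence),
                class = "host_usage_table")
    })
  })
}

#' Specification of a synthetic labeled plasmid genome
#'
#' A transmissible surrogate draws its codons from a mixture of several host
#' usage tables (a broad-host plasmid ameliorated toward multiple hosts); a
#' non-transmissible surrogate uses exactly one host table.
#'
#' @param n_genes Number of genes (`>= 1`).
#' @param gene_len_codons Integer range `c(min, max)` of internal codons per
#'   gene (start and stop added on top).
#' @param intergenic_frac Fraction of the genome that is intergenic, in
#'   `[0, 1)`.
#' @param usage_mixture List of host tables, or list of
#'   `list(table =, weight =)` pairs; weights must sum to 1 (equal weights
#'   assumed when bare tables are given).
#' @param label `"transmissible"` (requires >= 2 mixture components) or
#'   `"non-transmissible"` (exactly 1).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param genome_id Identifier.
#' @param mixing `"codon"` (default): each codon independently drawn from a
#'   mixture component, emulating within-gene amelioration blending;
#'   `"gene"`: one component drawn per gene.
#' @return An object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(n_genes, gene_len_codons, intergenic_frac,
                                  usage_mixture, label, seed,
                                  genome_id = "synthetic",
                                  mixing = c("codon", "gene")) {
  mixing <- match.arg(mixing)
  if (n_genes < 1L) stop("'n_genes' must be >= 1")
  if (intergenic_frac < 0 || intergenic_frac >= 1) {
    stop("'intergenic_frac' must be in [0, 1)")
  }
  label <- match.arg(label, c("transmissible", "non-transmissible"))
  if (inherits(usage_mixture, "host_usage_table")) {
    usage_mixture <- list(usage_mixture)
  }
  mix <- lapply(usage_mixture, function(cmp) {
    if (inherits(cmp, "host_usage_table")) {
      list(table = cmp, weight = 1 / length(usage_mixture))
    } else cmp
  })
  w <- vapply(mix, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (label == "transmissible" && length(mix) < 2L) {
    stop("a transmissible surrogate needs >= 2 mixture components")
  }
  if (label == "non-transmissible" && length(mix) != 1L) {
    stop("a non-transmissible surrogate uses exactly 1 component")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         gene_len_codons = as.integer(gene_len_codons),
         intergenic_frac = intergenic_frac,
         usage_mixture = mix, label = label, seed = as.integer(seed),
         genome_id = genome_id, mixing = mixing),
    class = "genome_spec"
  )
}

#' Generate a synthetic labeled plasmid genome
#'
#' Genes are drawn codon-by-codon from the spec's host usage mixture (amino
#' acids uniform over the 20 standard residues; ATG start, stop codon drawn
#' from the stop-category distribution), laid down on the forward strand and
#' separated by intergenic spacers of the configured G+C composition. CDS
#' coordinates are recorded so the genome supports annotation-based IEA
#' profiling and fragment labeling.
#'
#' @param spec A `genome_spec` from [synthetic_genome_spec()].
#' @param code A `genetic_code`.
#' @return A genome record: list with `genome_id`, `sequence`, `cds`
#'   (data.frame `cds_id`, `start`, `end`, `strand`; 1-based inclusive),
#'   `label`, `length`.
#' @export
synth_genome <- function(spec, code = build_genetic_code()) {
  stopifnot(inherits(spec, "genome_spec"))
  tables <- lapply(spec$usage_mixture, `[[`, "table")
  weights <- vapply(spec$usage_mixture, `[[`, numeric(1), "weight")
  aa_pool <- setdiff(names(tables[[1L]]$probs), "*")
  gc <- tables[[1L]]$gc_bias
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  withr::with_seed(spec$seed, {
    lens <- sample(spec$gene_len_codons[1L]:spec$gene_len_codons[2L],
                   spec$n_genes, replace = TRUE)
    genes <- vapply(seq_len(spec$n_genes), function(g) {
      n_int <- lens[g]
      comp <- if (spec$mixing == "gene") {
        rep(sample.int(length(tables), 1L, prob = weights), n_int + 1L)
      } else {
        sample.int(length(tables), n_int + 1L, replace = TRUE, prob = weights)
      }
      aas <- sample(aa_pool, n_int, replace = TRUE)
      codons <- vapply(seq_len(n_int), function(i) {
        p <- tables[[comp[i]]]$probs[[aas[i]]]
        sample(names(p), 1L, prob = p)
      }, character(1))
      pstop <- tables[[comp[n_int + 1L]]]$probs[["*"]]
      paste0("ATG", paste(codons, collapse = ""),
             sample(names(pstop), 1L, prob = pstop))
    }, character(1))

    coding_len <- sum(nchar(genes))
    total_inter <- round(spec$intergenic_frac / (1 - spec$intergenic_frac) *
                           coding_len)
    n_spacers <- spec$n_genes + 1L
    spacer_len <- diff(round(seq(0, total_inter, length.out = n_spacers + 1L)))
    spacers <- vapply(spacer_len, function(n) {
      if (n == 0L) return("")
      paste(sample(names(base_p), n, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))

    pieces <- character(2L * spec$n_genes + 1L)
    pieces[seq(1L, by = 2L, length.out = n_spacers)] <- spacers
    pieces[seq(2L, by = 2L, length.out = spec$n_genes)] <- genes
    sequence <- paste(pieces, collapse = "")

    pos <- 0L
    cds_start <- integer(spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      pos <- pos + nchar(spacers[g])
      cds_start[g] <- pos + 1L
      pos <- pos + nchar(genes[g])
    }
    cds <- data.frame(cds_id = sprintf("%s_g%03d", spec$genome_id,
                                       seq_len(spec$n_genes)),
                      start = cds_start,
                      end = cds_start + nchar(genes) - 1L,
                      strand = "+", stringsAsFactors = FALSE)
    list(genome_id = spec$genome_id, sequence = sequence, cds = cds,
         label = spec$label, length = nchar(sequence))
  })
}

#' Extract the nucleotide sequences of a genome's annotated CDS
#'
#' @param genome A genome record with a `cds` table (columns `cds_id`,
#'   `start`, `end`, `strand`; 1-based inclusive, parts of a joined CDS
#'   share a `cds_id` and are listed in order).
#' @return Named character vector of CDS sequences (minus-strand CDS
#'   reverse-complemented).
#' @export
cds_sequences <- function(genome) {
  cds <- genome$cds
  if (is.null(cds) || nrow(cds) == 0L) return(character(0))
  if (is.null(cds$cds_id)) cds$cds_id <- seq_len(nrow(cds))
  parts <- split(seq_len(nrow(cds)), factor(cds$cds_id, levels = unique(cds$cds_id)))
  vapply(parts, function(idx) {
    s <- paste(substring(genome$sequence, cds$start[idx], cds$end[idx]),
               collapse = "")
    if (cds$strand[idx[1L]] == "-") reverse_complement(s) else s
  }, character(1))
}

#' Randomly extract labeled fragments from a genome
#'
#' Fragment extraction in the style of a read/contig simulator: start
#' positions uniform over valid positions, lengths uniform over the range,
#' strand uniform, error-free copies (the intended targets are assembled
#' contigs). Fragments inherit the genome's class label. Coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param genome A genome record (needs `sequence`; `genome_id` and `label`
#'   are carried through).
#' @param length_range Integer `c(min, max)` fragment length in bp.
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @param group Benchmark group tag (`"train"`, `"A"`, `"B"`, `"C"`, `"D"`).
#' @return A `data.frame` with columns `fragment_id`, `genome_id`, `start`,
#'   `end`, `strand`, `length`, `label`, `group`, `sequence`.
#' @export
extract_fragments <- function(genome, length_range, n, seed = 1L,
                              group = "train") {
  L <- nchar(genome$sequence)
  if (L < length_range[2L]) {
    stop("genome ", genome$genome_id %||% "?", " (", L,
         " bp) shorter than the maximum fragment length ", length_range[2L])
  }
  withr::with_seed(as.integer(seed), {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                     integer(1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$sequence, starts + 1L, starts + lens)
    flip <- strands == "-"
    seqs[flip] <- vapply(seqs[flip], reverse_complement, character(1),
                         USE.NAMES = FALSE)
    data.frame(
      fragment_id = sprintf("%s_%s_f%06d", genome$genome_id %||% "genome",
                            group, seq_len(n)),
      genome_id = genome$genome_id %||% "genome",
      start = starts, end = starts + lens, strand = strands,
      length = lens, label = genome$label %||% NA_character_,
      group = group, sequence = seqs, stringsAsFactors = FALSE
    )
  })
}

#' Default benchmark configuration
#'
#' Fragment counts and length strata of the full-scale benchmark: 300 000
#' training fragments per class at 100-400 bp and per-class test sets of
#' 30 000 fragments in groups A (100-400 bp), B (401-800 bp) and
#' C (801-1200 bp) and 10 000 in group D (5000-10 000 bp). Desk-scale runs
#' override the counts.
#'
#' @param n_train_per_class,n_test_per_class Per-class fragment counts
#'   (`n_test_per_class` named by group).
#' @param seed Integer seed.
#' @return A list configuration for [build_benchmark()].
#' @export
benchmark_config <- function(n_train_per_class = 300000L,
                             n_test_per_class = c(A = 30000L, B = 30000L,
                                                  C = 30000L, D = 10000L),
                             seed = 1L) {
  list(
    n_train_per_class = n_train_per_class,
    n_test_per_class = n_test_per_class,
    train_range = c(100L, 400L),
    group_ranges = list(A = c(100L, 400L), B = c(401L, 800L),
                        C = c(801L, 1200L), D = c(5000L, 10000L)),
    seed = as.integer(seed)
  )
}

#' Build a class-balanced train/test fragment benchmark
#'
#' Genomes are split between training and test by their `split` field (in
#' real data this is the release-date split; synthetic genomes carry an
#' explicit assignment), so no genome contributes fragments to both sides.
#' Within each side, per-class fragment counts are divided evenly across
#' that class's genomes.
#'
#' @param genomes List of genome records, each with a `split` field
#'   (`"train"` or `"test"`) and a class `label`.
#' @param config Configuration from [benchmark_config()].
#' @return List with `train` (fragment data.frame), `test` (named list of
#'   fragment data.frames, one per group), and `manifest` (all fragments,
#'   sequence column dropped).
#' @export
build_benchmark <- function(genomes, config = benchmark_config()) {
  splits <- vapply(genomes, function(g) g$split %||% NA_character_, character(1))
  labels <- vapply(genomes, function(g) g$label %||% NA_character_, character(1))
  if (anyNA(splits) || anyNA(labels)) {
    stop("every genome needs a 'split' and a 'label' field")
  }
  classes <- c("transmissible", "non-transmissible")
  for (sp in c("train", "test")) {
    for (cl in classes) {
      if (!any(splits == sp & labels == cl)) {
        stop("class '", cl, "' absent from the ", sp, " split")
      }
    }
  }
  alloc <- function(total, k) {
    base <- total %/% k
    extra <- total %% k
    base + (seq_len(k) <= extra)
  }
  sample_side <- function(split, range, n_per_class, group) {
    out <- lapply(classes, function(cl) {
      gs <- genomes[splits == split & labels == cl]
      ns <- alloc(n_per_class, length(gs))
      do.call(rbind, lapply(seq_along(gs), function(i) {
        if (ns[i] == 0L) return(NULL)
        extract_fragments(gs[[i]], range, ns[i],
                          seed = (config$seed + 7919L * i +
                                    131L * utf8ToInt(substr(cl, 1L, 1L)) +
                                    sum(utf8ToInt(group))) %% .Machine$integer.max,
                          group = group)
      }))
    })
    do.call(rbind, out)
  }
  train <- sample_side("train", config$train_range,
                       config$n_train_per_class, "train")
  test <- lapply(names(config$group_ranges), function(g) {
    sample_side("test", config$group_ranges[[g]],
                config$n_test_per_class[[g]], g)
  })
  names(test) <- names(config$group_ranges)
  manifest <- do.call(rbind, c(list(train), test))
  manifest$sequence <- NULL
  list(train = train, test = test, manifest = manifest)
}

#' Write a benchmark to FASTA files and a manifest TSV
#'
#' @param benchmark Output of [build_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fa <- function(df, path) {
    x <- Biostrings::DNAStringSet(df$sequence)
    names(x) <- df$fragment_id
    Biostrings::writeXStringSet(x, path)
    path
  }
  paths <- c(train = write_fa(benchmark$train, file.path(dir, "train.fasta")))
  for (g in names(benchmark$test)) {
    paths[[paste0("group_", g)]] <-
      write_fa(benchmark$test[[g]], file.path(dir, sprintf("group_%s.fasta", g)))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(benchmark$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["manifest"]] <- manifest_path
  invisible(paths)
}
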