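# Deterministic synthetic-data generator. Produces every input the pipeline
# consumes -- genome pairs with planted 100%-identical elements on a
# divergent background, soft-masked repeat tracts, near-identical duplicated
# elements, per-taxon contigs diverged from the design genome, and qPCR Cp
# tables with known delta-Cp -- together with truth files, so the whole
# workflow can be exercised and checked without any external aligner.

#' Specification for the synthetic-data generator
#'
#' Defaults describe the study conditions the toolkit is exercised under:
#' a pair of 60 kb genomes sharing 50 planted, perfectly conserved elements
#' of 60-200 bp at least 500 bp apart on a background diverged at a 15%
#' substitution rate per genome, with optional near-identical duplicated
#' copies (default identity 0.90), soft-masked repeat tracts, contigs
#' diverged 5% from the design genome, and Cp tables with 2 replicates.
#'
#' @param genome_length length of each genome (bp).
#' @param n_elements number of planted conserved elements.
#' @param element_length_range inclusive range of element lengths.
#' @param n_duplicated_elements how many elements additionally receive a
#'   near-identical planted copy (each copy is its own truth interval).
#' @param duplicate_identity approximate identity of a duplicated copy.
#' @param background_substitution_rate per-genome substitution rate outside
#'   elements.
#' @param repeat_tracts list(count, length): lowercase tracts planted in the
#'   background of both genomes.
#' @param n_masked_elements lowercase (soft-mask) the first this-many
#'   elements entirely, to exercise the bait repeat filter.
#' @param min_spacing minimum gap between planted intervals (bp).
#' @param contig_divergence substitution rate applied to synthetic contigs.
#' @param contig_flank_max maximum random flank carried by a contig (bp).
#' @param maf_flank background flank included in each truth MAF block (bp).
#' @return validated list of class `synth_spec`.
#' @export
synth_spec <- function(genome_length = 60000, n_elements = 50,
                       element_length_range = c(60, 200),
                       n_duplicated_elements = 0, duplicate_identity = 0.90,
                       background_substitution_rate = 0.15,
                       repeat_tracts = list(count = 0, length = 300),
                       n_masked_elements = 0, min_spacing = 500,
                       contig_divergence = 0.05, contig_flank_max = 400,
                       maf_flank = 50) {
  spec <- list(genome_length = genome_length, n_elements = n_elements,
               element_length_range = element_length_range,
               n_duplicated_elements = n_duplicated_elements,
               duplicate_identity = duplicate_identity,
               background_substitution_rate = background_substitution_rate,
               repeat_tracts = repeat_tracts,
               n_masked_elements = n_masked_elements,
               min_spacing = min_spacing,
               contig_divergence = contig_divergence,
               contig_flank_max = contig_flank_max, maf_flank = maf_flank)
  stopifnot(background_substitution_rate >= 0, background_substitution_rate <= 1,
            contig_divergence >= 0, contig_divergence <= 1,
            duplicate_identity > 0, duplicate_identity <= 1,
            n_duplicated_elements <= n_elements,
            n_masked_elements <= n_elements,
            element_length_range[1] >= 1,
            element_length_range[2] >= element_length_range[1])
  structure(spec, class = "synth_spec")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute each position with probability `rate` (always to a different base)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(BASES, toupper(b)), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

replace_at <- function(seq, start, piece) {
  # 0-based start
  paste0(substr(seq, 1, start), piece,
         substr(seq, start + nchar(piece) + 1, nchar(seq)))
}

set_base <- function(seq, pos, base) replace_at(seq, pos, base)

lowercase_at <- function(seq, start, end) {
  replace_at(seq, start, tolower(substr(seq, start + 1, end)))
}

#' Generate a synthetic genome pair with planted conserved elements
#'
#' The ancestral background is mutated independently in each genome at the
#' background substitution rate, except inside planted elements, which are
#' copied verbatim into both genomes. Duplicated elements are planted as
#' additional near-identical intervals. When the background rate is
#' positive, the single background base flanking each element is forced to
#' differ between the genomes so that planted elements are exactly the
#' maximal conserved runs. The truth MAF contains one gapless block per
#' planted interval (element plus `maf_flank` background on each side), so
#' the conserved-region scan needs no external aligner.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed; identical (spec, seed) yields identical output
#'   bytes.
#' @param dir optional output directory; writes `genomeA.fasta`,
#'   `genomeB.fasta`, `truth.bed`, `truth.maf`.
#' @return list: `genome_a`, `genome_b` (named character vectors),
#'   `truth` (data.frame with chrom/start/end/name/type coordinates on
#'   genome A), `blocks` (truth MAF blocks), `paths` when `dir` is given.
#' @export
make_genome_pair <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  n_total <- spec$n_elements + spec$n_duplicated_elements
  len_choices <- seq(spec$element_length_range[1], spec$element_length_range[2])
  lens <- if (length(len_choices) == 1L) {
    rep(len_choices, spec$n_elements)
  } else {
    sample(len_choices, spec$n_elements, replace = TRUE)
  }
  elements <- vapply(lens, random_dna, character(1))

  dup_src <- seq_len(spec$n_duplicated_elements)
  dup_seqs <- vapply(dup_src, function(i) {
    mutate_seq(elements[i], 1 - spec$duplicate_identity)
  }, character(1))
  all_seqs <- c(elements, dup_seqs)
  all_names <- c(sprintf("elem-%d", seq_len(spec$n_elements)),
                 sprintf("elem-%d-dup", dup_src))
  all_types <- c(rep("element", spec$n_elements),
                 rep("duplicate-copy", length(dup_src)))
  all_lens <- nchar(all_seqs)

  need <- sum(all_lens) + (n_total + 1L) * spec$min_spacing
  if (need > spec$genome_length) {
    stop("infeasible packing: need genome_length >= ", need)
  }
  slack <- spec$genome_length - need
  u <- stats::runif(n_total + 1L)
  extra <- floor(slack * u / sum(u))
  gaps <- as.integer(spec$min_spacing + extra)
  starts <- integer(n_total)
  pos <- 0L
  for (i in seq_len(n_total)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + all_lens[i]
  }

  L <- spec$genome_length
  ancestor <- random_dna(L)
  rate <- spec$background_substitution_rate
  genome_a <- mutate_seq(ancestor, rate)
  genome_b <- mutate_seq(ancestor, rate)
  for (i in seq_len(n_total)) {
    genome_a <- replace_at(genome_a, starts[i], all_seqs[i])
    genome_b <- replace_at(genome_b, starts[i], all_seqs[i])
  }
  if (rate > 0) {
    # guarantee each planted interval is a maximal conserved run
    for (i in seq_len(n_total)) {
      for (pos in c(starts[i] - 1L, starts[i] + all_lens[i])) {
        if (pos < 0 || pos >= L) next
        a <- substr(genome_a, pos + 1, pos + 1)
        genome_b <- set_base(genome_b, pos, sample(setdiff(BASES, toupper(a)), 1))
      }
    }
  }
  # soft-masked repeat tracts in the background of both genomes
  if (spec$repeat_tracts$count > 0) {
    tlen <- spec$repeat_tracts$length
    placed <- 0L
    tries <- 0L
    while (placed < spec$repeat_tracts$count && tries < 1000L) {
      tries <- tries + 1L
      s <- sample.int(L - tlen, 1) - 1L
      clear <- all(s + tlen <= starts - spec$maf_flank |
                     s >= starts + all_lens + spec$maf_flank)
      if (!clear) next
      genome_a <- lowercase_at(genome_a, s, s + tlen)
      genome_b <- lowercase_at(genome_b, s, s + tlen)
      placed <- placed + 1L
    }
  }
  if (spec$n_masked_elements > 0) {
    for (i in seq_len(spec$n_masked_elements)) {
      genome_a <- lowercase_at(genome_a, starts[i], starts[i] + all_lens[i])
      genome_b <- lowercase_at(genome_b, starts[i], starts[i] + all_lens[i])
    }
  }

  fl <- spec$maf_flank
  blocks <- lapply(seq_len(n_total), function(i) {
    s <- max(0L, starts[i] - fl)
    e <- min(L, starts[i] + all_lens[i] + fl)
    maf_block(data.frame(
      src = c("genomeA", "genomeB"), start = c(s, s), size = c(e - s, e - s),
      strand = "+", src_size = c(L, L),
      text = c(slice0(genome_a, s, e), slice0(genome_b, s, e)),
      stringsAsFactors = FALSE))
  })
  truth <- data.frame(chrom = "genomeA", start = as.integer(starts),
                      end = as.integer(starts + all_lens), name = all_names,
                      type = all_types, stringsAsFactors = FALSE)
  out <- list(genome_a = c(genomeA = genome_a),
              genome_b = c(genomeB = genome_b),
              truth = truth, blocks = blocks)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome_a = file.path(dir, "genomeA.fasta"),
                  genome_b = file.path(dir, "genomeB.fasta"),
                  bed = file.path(dir, "truth.bed"),
                  maf = file.path(dir, "truth.maf"))
    write_fasta(out$genome_a, paths$genome_a)
    write_fasta(out$genome_b, paths$genome_b)
    write_bed(truth, paths$bed)
    write_maf(blocks, paths$maf)
    out$paths <- paths
  }
  out
}

#' Generate synthetic per-taxon contigs from design loci
#'
#' One contig per locus: the locus slice plus random flanks (up to
#' `contig_flank_max` each side), mutated iid at `divergence`. Optional
#' extras exercise the harvest screens: a second diverged contig for the
#' first `two_contig_loci` loci (triggering the duplicate-contig rule),
#' chimeric contigs concatenating two locus slices (triggering the
#' multi-locus rule), off-target decoy contigs from background sequence, and
#' reverse-complementation of every other contig.
#'
#' @param genome named character vector (design genome).
#' @param loci data.frame with `locus_id`, `chrom`, `start`, `end`.
#' @param divergence contig substitution rate.
#' @param seed integer seed.
#' @param flank_max maximum random flank (bp).
#' @param two_contig_loci,n_chimeras,n_decoys extra-contig counts.
#' @param revcomp_alternate reverse-complement every second contig.
#' @param path optional FASTA output path.
#' @return list: `contigs` (named character vector) and `truth`
#'   (contig_id, locus_id, type).
#' @export
make_contigs <- function(genome, loci, divergence, seed, flank_max = 400,
                         two_contig_loci = 0, n_chimeras = 0, n_decoys = 0,
                         revcomp_alternate = TRUE, path = NULL) {
  set.seed(seed)
  stopifnot(nrow(loci) >= 1)
  contigs <- character(0)
  truth <- data.frame(contig_id = character(), locus_id = character(),
                      type = character(), stringsAsFactors = FALSE)
  k <- 0L
  add <- function(seq, locus, type) {
    k <<- k + 1L
    id <- sprintf("node_%d", k)
    if (revcomp_alternate && k %% 2L == 0L) seq <- revcomp(seq)
    contigs[[id]] <<- seq
    truth <<- rbind(truth, data.frame(contig_id = id, locus_id = locus,
                                      type = type, stringsAsFactors = FALSE))
  }
  locus_slice <- function(i, fuzz = TRUE) {
    chrom <- loci$chrom[i]
    glen <- nchar(genome[[chrom]])
    f5 <- if (fuzz) sample(0:flank_max, 1) else 0L
    f3 <- if (fuzz) sample(0:flank_max, 1) else 0L
    slice0(genome[[chrom]], max(0L, loci$start[i] - f5),
           min(glen, loci$end[i] + f3))
  }
  for (i in seq_len(nrow(loci))) {
    add(mutate_seq(toupper(locus_slice(i)), divergence), loci$locus_id[i],
        "target")
    if (i <= two_contig_loci) {
      add(mutate_seq(toupper(locus_slice(i)), divergence), loci$locus_id[i],
          "extra-copy")
    }
  }
  if (n_chimeras > 0) {
    # chimeras join the last loci so the duplicate-contig and multi-locus
    # screens are exercised on distinct loci
    for (j in seq_len(n_chimeras)) {
      i1 <- nrow(loci) - 2L * j + 1L
      i2 <- nrow(loci) - 2L * j + 2L
      stopifnot(i1 >= 1)
      add(mutate_seq(toupper(paste0(locus_slice(i1, fuzz = FALSE),
                                    locus_slice(i2, fuzz = FALSE))), divergence),
          paste(loci$locus_id[c(i1, i2)], collapse = "+"), "chimera")
    }
  }
  if (n_decoys > 0) {
    for (j in seq_len(n_decoys)) {
      add(random_dna(sample(300:800, 1)), NA_character_, "decoy")
    }
  }
  if (!is.null(path)) write_fasta(contigs, path)
  list(contigs = contigs, truth = truth)
}

#' Generate a synthetic qPCR Cp table with known truth folds
#'
#' Unenriched replicate Cp values are `base_cp` plus Gaussian noise;
#' enriched values are shifted by the supplied per-library delta-Cp (an
#' earlier crossing point for successful enrichment). Truth folds follow
#' the closed form `efficiency^|delta_cp|`.
#'
#' @param delta_cp named numeric vector: library -> delta Cp.
#' @param blockers named character vector: library -> blocker label.
#' @param amplicons character vector of amplicon names.
#' @param base_cp unenriched mean Cp, default 25.
#' @param noise_sd replicate noise SD (0 for exact truth), default 0.
#' @param replicates replicates per record, default 2.
#' @param efficiency assumed amplification efficiency for truth folds.
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return list: `cp` (wide data.frame as read by [enrichment_folds()]) and
#'   `truth` (library, amplicon, blocker, delta_cp, fold).
#' @export
make_cp_table <- function(delta_cp, blockers, amplicons = paste0("amp", 1:7),
                          base_cp = 25, noise_sd = 0, replicates = 2,
                          efficiency = 1.78, seed = 1, path = NULL) {
  set.seed(seed)
  stopifnot(!is.null(names(delta_cp)), all(names(delta_cp) %in% names(blockers)))
  cp <- NULL
  truth <- NULL
  for (lib in names(delta_cp)) {
    for (amp in amplicons) {
      un <- round(base_cp + stats::rnorm(replicates, 0, noise_sd), 4)
      en <- round(base_cp - delta_cp[[lib]] + stats::rnorm(replicates, 0, noise_sd), 4)
      reps <- function(x) as.data.frame(as.list(setNames(x, paste0("rep",
                                                                  seq_along(x)))))
      cp <- rbind(cp,
                  cbind(data.frame(library = lib, amplicon = amp,
                                   treatment = "enriched",
                                   blocker = blockers[[lib]],
                                   stringsAsFactors = FALSE), reps(en)),
                  cbind(data.frame(library = lib, amplicon = amp,
                                   treatment = "unenriched",
                                   blocker = blockers[[lib]],
                                   stringsAsFactors = FALSE), reps(un)))
      truth <- rbind(truth, data.frame(
        library = lib, amplicon = amp, blocker = blockers[[lib]],
        delta_cp = -delta_cp[[lib]], fold = efficiency^abs(delta_cp[[lib]]),
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(path)) write.csv(cp, path, row.names = FALSE)
  list(cp = cp, truth = truth)
}

#' Generate synthetic per-taxon capture covariates with known coefficients
#'
#' Draws covariates and responses from the generative models the
#' capture-success GLMs assume: Poisson counts with
#' `log(mu) = b0 + b1 * distance` and Gaussian lengths. Used for parameter
#' recovery checks.
#'
#' @param n number of taxa.
#' @param b0,b1 intercept and distance coefficient on the log scale.
#' @param seed integer seed.
#' @return data.frame with `distance`, `reads`, `mean_read_length`,
#'   `assembly_method`, `uce_count`, `mean_uce_length`.
#' @export
make_capture_data <- function(n = 200, b0 = 2, b1 = 3, seed = 1) {
  set.seed(seed)
  distance <- stats::runif(n, 0, 1)
  reads <- stats::rpois(n, 5e5)
  mean_read_length <- stats::rnorm(n, 140, 10)
  assembly_method <- sample(c("trinity", "abyss"), n, replace = TRUE)
  mu <- exp(b0 + b1 * distance)
  uce_count <- stats::rpois(n, mu)
  mean_uce_length <- stats::rnorm(n, 800 - 300 * distance, 50)
  data.frame(taxon = sprintf("taxon%03d", seq_len(n)), distance = distance,
             reads = reads, mean_read_length = mean_read_length,
             assembly_method = assembly_method, uce_count = uce_count,
             mean_uce_length = mean_uce_length, stringsAsFactors = FALSE)
}
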