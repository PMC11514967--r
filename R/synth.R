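## Synthetic two-class datasets with planted, independently tunable signals
## in each of the three feature channels (core-motif positions, regional
## k-mer composition, regional co-factor occurrences) over a 0-order
## background — the validation substrate for every module and for the
## end-to-end pipeline.

#' Bundled synthetic PWM library
#'
#' Ten short synthetic motifs (JASPAR PFM text fixture shipped with the
#' package) standing in for a co-factor motif library in examples and
#' validation runs. These are generated motifs, not curated ones.
#'
#' @return named list of [ppm]s.
#' @export
synthetic_pfm_library <- function() {
  read_jaspar_library(system.file("extdata", "pfms",
                                  "synthetic_library.pfm",
                                  package = "motifcontrast",
                                  mustWork = TRUE))
}

## Sharp PPM around a consensus string.
consensus_ppm <- function(consensus, p = 0.85, name = consensus) {
  v <- match(strsplit(consensus, "")[[1]], NUCS)
  probs <- matrix((1 - p) / 3, 4, length(v))
  probs[cbind(v, seq_along(v))] <- p
  ppm(probs, name = name)
}

#' Configuration of the synthetic dataset generator
#'
#' Defaults define the reference validation conditions: 1000 sequences per
#' class of length 1000 bp over a uniform 0-order background; a sharp 10-bp
#' core motif (0.95 consensus probability per position, so nearly every
#' planted site passes a FIMO-style hit threshold, matching the few-percent
#' discard rate seen in practice) planted within +/- 50 bp of the nominal summit (so anchoring does
#' real work) with 2% dropout; one core position where class 1 carries A
#' with probability 0.8 and class 2 with probability 0.2; one k-mer (ACA)
#' enriched 1.4-fold in class 1 over \[-150, 500); and one co-factor motif
#' planted in \[-250, 0) with probability 0.85 in class 1 vs 0.15 in class 2
#' (the co-factor is planted at higher contrast than the core position
#' because regional k-mer composition partially proxies motif presence, so
#' part of the co-factor signal is shared with the environment channel).
#' The three channels are deliberately of comparable moderate strength
#' (single-channel AUROC roughly 0.75-0.85) so that the combined model stays
#' off the AUROC ceiling and group ablations are informative.
#' Every element can be overridden or removed (empty list = no signal in
#' that channel).
#'
#' @param n_per_class sequences per class.
#' @param seq_length aligned sequence length (bp).
#' @param background A/C/G/T probabilities of the 0-order background.
#' @param core_ppm [ppm] of the planted core motif.
#' @param dm_positions list of `list(position, class1, class2)`: 1-based
#'   core position and per-class nucleotide probability 4-vectors.
#' @param ne_signals list of `list(kmer, rel_start, rel_end, factor1,
#'   factor2)`: per-class multiplicative enrichment of the k-mer frequency
#'   in the anchor-relative region.
#' @param cf_signals list of `list(ppm, rel_start, rel_end, prob1, prob2)`:
#'   per-class probability of planting one motif occurrence in the region.
#' @param motif_dropout fraction of sequences with no core motif.
#' @param summit_jitter max |offset| of the core midpoint from the summit.
#' @param seed RNG seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_per_class = 1000L, seq_length = 1000L,
                         background = rep(0.25, 4),
                         core_ppm = consensus_ppm("TGCATAAGGT", p = 0.95,
                                                  name = "core"),
                         dm_positions = list(list(
                           position = 3L,
                           class1 = c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3),
                           class2 = c(0.2, 0.8 / 3, 0.8 / 3, 0.8 / 3))),
                         ne_signals = list(list(
                           kmer = "ACA", rel_start = -150L, rel_end = 500L,
                           factor1 = 1.4, factor2 = 1)),
                         cf_signals = NULL,
                         motif_dropout = 0.02,
                         summit_jitter = 50L,
                         seed = 1L) {
  if (is.null(cf_signals))
    cf_signals <- list(list(ppm = synthetic_pfm_library()[[1L]],
                            rel_start = -250L, rel_end = 0L,
                            prob1 = 0.85, prob2 = 0.15))
  dm_positions <- lapply(dm_positions, function(d) {
    d$class1 <- d$class1 / sum(d$class1)
    d$class2 <- d$class2 / sum(d$class2)
    stopifnot(d$position >= 1L, d$position <= ncol(core_ppm$probs))
    d
  })
  stopifnot(motif_dropout >= 0, motif_dropout < 1,
            abs(sum(background) - 1) < 1e-8)
  structure(list(n_per_class = n_per_class, seq_length = seq_length,
                 background = background, core_ppm = core_ppm,
                 dm_positions = dm_positions, ne_signals = ne_signals,
                 cf_signals = cf_signals, motif_dropout = motif_dropout,
                 summit_jitter = summit_jitter, seed = seed),
            class = "synth_config")
}

sample_site <- function(probs) {
  K <- ncol(probs)
  idx <- vapply(seq_len(K), function(k)
    sample.int(4L, 1L, prob = probs[, k]), 1L)
  NUCS[idx]
}

## Generate one locus (letter vector) of length `locus_len` with the core
## midpoint at `core_mid` (locus coordinates, 1-based), carrying the class'
## planted signals. Returns NULL core position when the core is dropped out.
generate_locus <- function(cfg, cls, locus_len, core_mid) {
  bg <- cfg$background
  letters_ <- sample(NUCS, locus_len, replace = TRUE, prob = bg)
  K <- ncol(cfg$core_ppm$probs)
  core_start <- core_mid - K %/% 2L # 1-based
  has_core <- stats::runif(1) >= cfg$motif_dropout
  core_span <- if (has_core) core_start:(core_start + K - 1L) else integer(0)
  if (has_core) {
    probs <- cfg$core_ppm$probs
    for (d in cfg$dm_positions)
      probs[, d$position] <- if (cls == 1L) d$class1 else d$class2
    letters_[core_span] <- sample_site(probs)
  }
  ## k-mer enrichment: multiply the expected regional frequency by the class
  ## factor — plant extra occurrences (f > 1) or disrupt existing ones
  ## (f < 1) at positions not overlapping the core
  for (s in cfg$ne_signals) {
    f <- if (cls == 1L) s$factor1 else s$factor2
    if (f == 1) next
    k <- nchar(s$kmer)
    kv <- strsplit(toupper(s$kmer), "")[[1]]
    lo <- core_mid + s$rel_start; hi <- core_mid + s$rel_end - 1L
    lo <- max(lo, 1L); hi <- min(hi, locus_len)
    starts <- lo:(hi - k + 1L)
    ok <- vapply(starts, function(st)
      !any((st:(st + k - 1L)) %in% core_span), TRUE)
    starts <- starts[ok]
    if (f > 1) {
      mu <- prod(cfg$background[match(kv, NUCS)])
      p_extra <- min(1, (f - 1) * mu)
      n_extra <- stats::rbinom(1L, length(starts), p_extra)
      if (n_extra > 0)
        for (st in sample(starts, n_extra))
          letters_[st:(st + k - 1L)] <- kv
    } else {
      for (st in starts) {
        if (all(letters_[st:(st + k - 1L)] == kv) &&
            stats::runif(1) > f) {
          pos <- st + sample.int(k, 1L) - 1L
          letters_[pos] <- sample(setdiff(NUCS, letters_[pos]), 1L)
        }
      }
    }
  }
  for (s in cfg$cf_signals) {
    p <- if (cls == 1L) s$prob1 else s$prob2
    if (stats::runif(1) >= p) next
    kc <- ncol(s$ppm$probs)
    lo <- core_mid + s$rel_start; hi <- core_mid + s$rel_end - 1L
    lo <- max(lo, 1L); hi <- min(hi, locus_len - kc + 1L)
    starts <- lo:(hi - kc + 1L)
    ok <- vapply(starts, function(st)
      !any((st:(st + kc - 1L)) %in% core_span), TRUE)
    starts <- starts[ok]
    if (length(starts) == 0L) next
    st <- if (length(starts) == 1L) starts else sample(starts, 1L)
    letters_[st:(st + kc - 1L)] <- sample_site(s$ppm$probs)
  }
  list(letters = letters_, core_start = if (has_core) core_start else NA)
}

#' Generate a synthetic two-class dataset
#'
#' Builds `2 * n_per_class` loci with planted signals per [synth_config],
#' assembles them into a toy two-chromosome genome with one ChIP-seq-style
#' peak per locus (summit at the locus centre, the core motif jittered
#' around it), and also returns ready-aligned sequences centred on the true
#' core midpoint (what perfect anchoring would produce; core-dropout loci
#' are excluded there, mirroring the anchoring drop).
#'
#' @param cfg a [synth_config].
#' @param dir optional directory: writes `genome.fa`, `class1.bed`,
#'   `class2.bed` and `truth.json` for the file-based pipeline path.
#' @return list with `aligned` ([aligned_seqs]), `genome` (`DNAStringSet`),
#'   `peaks` (list of two [peak_set]s), `truth` (planted ground-truth
#'   record) and, when `dir` is given, `files`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- ncol(cfg$core_ppm$probs)
  half <- cfg$seq_length %/% 2L
  locus_len <- cfg$seq_length + 2L * (cfg$summit_jitter + K + 2L)
  center <- locus_len %/% 2L
  with_seed(cfg$seed, {
    res <- list()
    for (cls in 1:2) {
      jit <- sample(seq(-cfg$summit_jitter, cfg$summit_jitter),
                    cfg$n_per_class, replace = TRUE)
      loci <- lapply(seq_len(cfg$n_per_class), function(i)
        generate_locus(cfg, cls, locus_len, center + jit[i]))
      res[[cls]] <- list(loci = loci, jit = jit)
    }
  })
  chroms <- c("chr1", "chr2")
  genome <- character(2)
  peaks <- list(); aligned <- list()
  truth_core <- list()
  for (cls in 1:2) {
    seq_cat <- vapply(res[[cls]]$loci, function(l)
      paste(l$letters, collapse = ""), "")
    genome[cls] <- paste(seq_cat, collapse = "")
    offs <- (seq_along(seq_cat) - 1L) * locus_len # 0-based locus starts
    summit <- offs + center # 0-based: locus position center+1 is 1-based
    peaks[[cls]] <- peak_set(chrom = chroms[cls],
                             start = summit - 200L, end = summit + 200L,
                             summit = summit,
                             genome_id = "synthetic")
    cs <- vapply(res[[cls]]$loci, function(l) as.integer(l$core_start), 1L)
    has <- !is.na(cs)
    core_mid <- cs + K %/% 2L # 1-based locus coords
    win_from <- core_mid - half # 1-based
    sq <- substr(rep(seq_cat[has], 1L), win_from[has],
                 win_from[has] + cfg$seq_length - 1L)
    aligned[[cls]] <- aligned_seqs(
      seq = sq, label = paste0("class", cls),
      chrom = chroms[cls],
      anchor = offs[has] + core_mid[has] - 1L,
      strand = "+",
      core_start = half + 1L - K %/% 2L,
      core_width = K)
    truth_core[[cls]] <- list(planted = sum(has),
                              dropped = sum(!has))
  }
  names(genome) <- chroms
  genome <- Biostrings::DNAStringSet(genome)
  al <- rbind_aligned(aligned[[1]], aligned[[2]])
  al$label <- factor(al$label, levels = c("class1", "class2"))
  truth <- list(
    core_consensus = consensus_seq(cfg$core_ppm),
    core_width = K,
    dm_positions = lapply(cfg$dm_positions, function(d)
      list(position = d$position, class1 = d$class1, class2 = d$class2)),
    ne_signals = lapply(cfg$ne_signals, function(s)
      s[c("kmer", "rel_start", "rel_end", "factor1", "factor2")]),
    cf_signals = lapply(cfg$cf_signals, function(s)
      list(pwm = s$ppm$name, rel_start = s$rel_start, rel_end = s$rel_end,
           prob1 = s$prob1, prob2 = s$prob2)),
    motif_dropout = cfg$motif_dropout,
    per_class = truth_core,
    seed = cfg$seed)
  out <- list(aligned = al, genome = genome, peaks = peaks, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa)
    b1 <- file.path(dir, "class1.bed"); b2 <- file.path(dir, "class2.bed")
    write_bed(peaks[[1]], b1); write_bed(peaks[[2]], b2)
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$files <- c(genome = fa, class1 = b1, class2 = b2, truth = tj)
  }
  out
}

#' Synthetic importance-profile fixtures
#'
#' Draws 3-vector ablation-importance profiles around three centroids
#' matching the regimes seen across paired-experiment runs — co-factors
#' dominant, core motif + co-factors, and nucleotidic environment +
#' co-factors — for validating the profile clustering.
#'
#' @param k number of regimes (1 to 3).
#' @param n total number of profiles.
#' @param noise Gaussian sd around the centroids.
#' @param seed RNG seed.
#' @return list with `profiles` (n x 3 matrix, columns DM/NE/CF) and
#'   `labels` (true regime per row).
#' @export
importance_profile_fixtures <- function(k = 3L, n = 60L, noise = 0.01,
                                        seed = 1L) {
  stopifnot(k >= 1L, k <= 3L, n >= 3L * k)
  centroids <- rbind(cf_dominant = c(0.01, 0.01, 0.15),
                     dm_plus_cf = c(0.12, 0.01, 0.05),
                     ne_plus_cf = c(0.01, 0.10, 0.05))[seq_len(k), ,
                                                       drop = FALSE]
  labels <- rep_len(seq_len(k), n)
  profiles <- with_seed(seed,
    centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(3L * n, sd = noise), n, 3L))
  colnames(profiles) <- c("DM", "NE", "CF")
  list(profiles = profiles, labels = labels)
}
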