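# Synthetic proteome generator.  Emits sequences, lysine site labels and
# PSSM/ASA/SS profiles carrying the statistical structure the predictor
# exploits: positives get enriched residues at chosen window offsets
# (including offsets far from the site), locally elevated solvent
# accessibility, and a coil/helix bias in secondary structure; PSSMs are
# pseudo-count log-odds of the emitted sequence plus integer-rounded noise,
# so they correlate with local composition the way alignment-derived
# profiles do.  Fully deterministic given the seed.

#' Default simulation parameters
#'
#' The defaults define the reference synthetic conditions: uniform 1/20
#' background composition, proteins of 200-400 residues, one fifth of
#' lysines ubiquitylated, acidic-residue (D/E) enrichment of strength 0.8
#' planted at offsets -16, -10, -3, -1, +1, +5, +13, +17, a 10-point mean
#' ASA elevation and a 0.5 coil/helix bias around positive sites, and
#' unit-sd PSSM noise.
#'
#' @return A named list of parameters accepted by [simulate_proteome()].
#' @export
sim_params <- function() {
  list(n_proteins = 50L,
       length_range = c(200L, 400L),
       background = stats::setNames(rep(1 / 20, 20), AA_ORDER),
       positive_rate = 0.2,
       signal_offsets = c(-16L, -10L, -3L, -1L, 1L, 5L, 13L, 17L),
       signal_residues = c("D", "E"),
       signal_strength = 0.8,
       asa_shift = 10,
       ss_coil_bias = 0.5,
       pssm_noise_sd = 1)
}

#' Generate a synthetic proteome with planted site signal
#'
#' @param n_proteins Number of proteins.
#' @param length_range Two-element integer range of protein lengths
#'   (uniform).
#' @param background Length-20 residue frequency vector in [AA_ORDER]
#'   order; must sum to 1.
#' @param positive_rate Probability that a lysine is a positive site.
#' @param signal_offsets Window offsets (within -20..+20, excluding 0) at
#'   which positives carry residue enrichment.
#' @param signal_residues Residues enriched at the signal offsets.
#' @param signal_strength Probability in `[0, 1]` that a signal-offset
#'   residue of a positive window is replaced by a signal residue.
#' @param asa_shift Mean percent-ASA elevation applied at offsets -5..+5
#'   around positive sites.
#' @param ss_coil_bias Probability that a residue at offsets -5..+5 around
#'   a positive site is rewritten to coil (70%) or helix (30%).
#' @param pssm_noise_sd Standard deviation of the Gaussian noise added to
#'   the synthetic log-odds before integer rounding.
#' @param n_pos_sites,n_neg_sites Optional exact site counts; the site
#'   table is subsampled to these sizes (error if the proteome yields
#'   fewer).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `"ub_sim"`: list with `prot` (protein
#'   table), `sites` (annotations), `profiles` (per-protein `pssm`, `asa`,
#'   `ss`), and `truth` (all parameters plus the planted positive sites).
#' @export
simulate_proteome <- function(n_proteins = 50L,
                              length_range = c(200L, 400L),
                              background = NULL,
                              positive_rate = 0.2,
                              signal_offsets = c(-16L, -10L, -3L, -1L,
                                                 1L, 5L, 13L, 17L),
                              signal_residues = c("D", "E"),
                              signal_strength = 0.8,
                              asa_shift = 10,
                              ss_coil_bias = 0.5,
                              pssm_noise_sd = 1,
                              n_pos_sites = NULL, n_neg_sites = NULL,
                              seed = 1L) {
  if (is.null(background)) background <- sim_params()$background
  stopifnot(abs(sum(background) - 1) < 1e-9,
            all(abs(signal_offsets) <= 20L), all(signal_offsets != 0L),
            signal_strength >= 0, signal_strength <= 1,
            positive_rate >= 0, positive_rate <= 1)
  with_seed(seed, {
    ids <- sprintf("SP%04d", seq_len(n_proteins))
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    seqs <- character(n_proteins)
    pos_sites <- list()
    for (i in seq_len(n_proteins)) {
      ch <- sample(AA_ORDER, lens[i], replace = TRUE, prob = background)
      kpos <- which(ch == "K")
      centers <- kpos[stats::runif(length(kpos)) < positive_rate]
      # plant residue enrichment around each positive center, never
      # touching a chosen center itself
      for (cpos in centers) {
        for (off in signal_offsets) {
          p <- cpos + off
          if (p >= 1L && p <= lens[i] && !(p %in% centers) &&
              stats::runif(1) < signal_strength) {
            ch[p] <- sample(signal_residues, 1)
          }
        }
      }
      seqs[i] <- paste(ch, collapse = "")
      # planting can overwrite non-center lysines, so re-derive the census
      pos_sites[[i]] <- intersect(centers, which(ch == "K"))
    }
    prot <- proteins(ids, seqs)
    if (sum(lengths(pos_sites)) == 0L && positive_rate > 0 &&
        sum(vapply(strsplit(seqs, ""), function(s) sum(s == "K"),
                   integer(1))) == 0L) {
      stop("proteome contains no lysines; positive_rate is unsatisfiable")
    }
    sites <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
      pos <- data.frame(protein_id = rep(ids[i], length(pos_sites[[i]])),
                        position = as.integer(pos_sites[[i]]),
                        label = rep("positive", length(pos_sites[[i]])),
                        stringsAsFactors = FALSE)
      rbind(pos, enumerate_negative_sites(prot, ids[i], pos_sites[[i]]))
    }))
    rownames(sites) <- NULL
    if (!is.null(n_pos_sites) || !is.null(n_neg_sites)) {
      sites <- .subsample_sites(sites, n_pos_sites, n_neg_sites)
    }
    profiles <- stats::setNames(lapply(seq_len(n_proteins), function(i) {
      .simulate_profiles(seqs[i], pos_sites[[i]], background,
                         asa_shift, ss_coil_bias, pssm_noise_sd)
    }), ids)
    truth <- list(seed = seed, n_proteins = n_proteins,
                  length_range = length_range,
                  background = as.list(background),
                  positive_rate = positive_rate,
                  signal_offsets = signal_offsets,
                  signal_residues = signal_residues,
                  signal_strength = signal_strength,
                  asa_shift = asa_shift, ss_coil_bias = ss_coil_bias,
                  pssm_noise_sd = pssm_noise_sd,
                  positive_sites = stats::setNames(pos_sites, ids))
    structure(list(prot = prot, sites = sites, profiles = profiles,
                   truth = truth),
              class = "ub_sim")
  })
}

.subsample_sites <- function(sites, n_pos, n_neg) {
  pick <- function(lab, want) {
    idx <- which(sites$label == lab)
    if (is.null(want)) return(idx)
    if (length(idx) < want) {
      stop("proteome yields only ", length(idx), " ", lab,
           " sites; ", want, " requested")
    }
    sort(sample(idx, want))
  }
  out <- sites[c(pick("positive", n_pos), pick("negative", n_neg)), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-protein PSSM (windowed pseudo-count log-odds + noise, integer),
# ASA (truncated normal percent, elevated near positives) and SS
# (run-structured states, coil/helix-rewritten near positives)
.simulate_profiles <- function(sequence, centers, background,
                               asa_shift, ss_coil_bias, pssm_noise_sd) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  near <- rep(FALSE, L)
  for (cpos in centers) {
    idx <- max(1L, cpos - 5L):min(L, cpos + 5L)
    near[idx] <- TRUE
  }
  # PSSM: counts of each residue in a +-3 window, pseudo-count 1,
  # log2 odds vs background, doubled (half-bit units), noise, rounded
  pssm <- matrix(0, L, 20, dimnames = list(NULL, AA_ORDER))
  for (p in seq_len(L)) {
    win <- ch[max(1L, p - 3L):min(L, p + 3L)]
    counts <- table(factor(win, levels = AA_ORDER))
    f <- (as.numeric(counts) + 1) / (length(win) + 20)
    pssm[p, ] <- round(2 * log2(f / background) +
                         stats::rnorm(20, sd = pssm_noise_sd))
  }
  asa <- stats::rnorm(L, mean = 35 + ifelse(near, asa_shift, 0), sd = 15)
  asa <- round(pmin(100, pmax(0, asa)), 1)
  ss <- .markov_ss(L)
  rewrite <- near & stats::runif(L) < ss_coil_bias
  ss[rewrite] <- sample(c("C", "H"), sum(rewrite), replace = TRUE,
                        prob = c(0.7, 0.3))
  list(pssm = pssm, asa = asa, ss = paste(ss, collapse = ""))
}

# run-structured secondary-structure string: states drawn with realistic
# marginals, geometric run lengths (mean ~6)
.markov_ss <- function(L) {
  out <- character(0)
  while (length(out) < L) {
    state <- sample(c("H", "E", "C"), 1, prob = c(0.35, 0.2, 0.45))
    out <- c(out, rep(state, 1L + stats::rgeom(1, 1 / 6)))
  }
  out[seq_len(L)]
}

#' @export
print.ub_sim <- function(x, ...) {
  cat("Synthetic proteome: ", nrow(x$prot), " proteins, ",
      sum(x$sites$label == "positive"), " positive / ",
      sum(x$sites$label == "negative"), " negative lysine sites\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic proteome to disk in the package's input formats
#'
#' Emits `proteins.fasta`, `sites.tsv`, per-protein `pssm/<id>.tsv`,
#' `asa/<id>.txt`, `ss/<id>.txt`, and `truth.yaml`.  Output is
#' byte-identical across runs for the same simulation object.
#'
#' @param sim An object from [simulate_proteome()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_proteome <- function(sim, dir) {
  for (d in file.path(dir, c("", "pssm", "asa", "ss"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  write_fasta(sim$prot, file.path(dir, "proteins.fasta"))
  write_site_annotations(sim$sites, file.path(dir, "sites.tsv"))
  for (id in sim$prot$id) {
    p <- sim$profiles[[id]]
    write_pssm_profile(p$pssm, file.path(dir, "pssm", paste0(id, ".tsv")))
    write_asa_profile(p$asa, file.path(dir, "asa", paste0(id, ".txt")))
    write_ss_profile(p$ss, file.path(dir, "ss", paste0(id, ".txt")))
  }
  yaml::write_yaml(sim$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a proteome directory written by [write_proteome()]
#'
#' @param dir Directory containing `proteins.fasta`, `sites.tsv` and the
#'   `pssm/`, `asa/`, `ss/` profile subdirectories.
#' @return A list with `prot`, `sites` and `profiles` in the same layout
#'   as [simulate_proteome()] output.
#' @export
read_proteome <- function(dir) {
  prot <- read_fasta(file.path(dir, "proteins.fasta"))
  sites <- read_site_annotations(file.path(dir, "sites.tsv"), prot)
  profiles <- stats::setNames(lapply(seq_len(nrow(prot)), function(i) {
    id <- prot$id[i]
    L <- prot$length[i]
    list(pssm = read_pssm_profile(file.path(dir, "pssm",
                                            paste0(id, ".tsv")),
                                  expected_length = L),
         asa = read_asa_profile(file.path(dir, "asa", paste0(id, ".txt")),
                                expected_length = L),
         ss = read_ss_profile(file.path(dir, "ss", paste0(id, ".txt")),
                              expected_length = L))
  }), prot$id)
  list(prot = prot, sites = sites, profiles = profiles)
}

#' Two labeled Gaussian clouds with controllable separation
#'
#' Classic classifier fixture: `n_per_class` points per class in `d`
#' dimensions, class means separated by `margin` in every coordinate
#' (Euclidean separation `margin * sqrt(d)`), unit within-class spread.
#'
#' @param n_per_class Points per class.
#' @param d Dimension.
#' @param margin Per-coordinate mean separation (>= 0).
#' @param seed Integer seed.
#' @return A list with `x` (`2*n_per_class` x `d` matrix) and `labels`.
#' @export
make_separable_set <- function(n_per_class, d, margin, seed = 1L) {
  stopifnot(margin >= 0)
  with_seed(seed, {
    xn <- matrix(stats::rnorm(n_per_class * d), n_per_class, d)
    xp <- matrix(stats::rnorm(n_per_class * d, mean = margin),
                 n_per_class, d)
    list(x = rbind(xn, xp),
         labels = rep(c("negative", "positive"), each = n_per_class))
  })
}
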