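# Synthetic locus, chromatin and bait-capture read simulation with planted
# ground truth. The generator emulates the statistical structure the analysis
# assumes: a V gene region with mixed orientations and a two-component RIC
# score mixture; planted Background/Architectural/Enhancer chromatin segments
# emitting negative-binomial binned counts; and paired-end reads carrying a
# 6-nt molecular identifier + anchor on read 1 and a J-specific bait on
# read 2, with chimaeras, PCR duplicates and unrecombined fragments.

#' Simulation configuration
#'
#' Returns the default study conditions; any field can be overridden by name.
#' Defaults: 162 V genes on a 700 kb locus (a scaled-down single-locus stand-in
#' for the 3.2 Mb kappa locus), ~55% reverse-strand genes, three replicates of
#' 45,000 unique molecules with J1-biased J usage (40%), 30% PCR duplication,
#' 65% unrecombined fragments and a 5% chimaera rate. Activity is logistic in
#' the RIC score and PU.1 binding at the RSS (with a weaker enhancer-state
#' term); log2 recombination frequency of active genes is linear in the RIC
#' score and the local enrichment of H3K4me2, H3K4me3 and IKAROS at the RSS,
#' with Gaussian noise.
#'
#' @param ... named overrides of any default field.
#' @return object of class `kappa_config`.
#' @export
sim_config <- function(...) {
  tracks <- c("Nuclear_RNA", "DHS", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac",
              "H3K27me3", "CTCF", "RAD21", "P300", "PAX5", "YY1", "PU.1",
              "MED1", "EBF1", "IRF4", "E2A", "BRG1", "IKAROS")
  enhancer <- setdiff(tracks, c("H3K27me3", "CTCF", "RAD21"))
  e_mult <- stats::setNames(rep(1, length(tracks)), tracks)
  e_mult[enhancer] <- 6
  e_mult[c("CTCF", "RAD21")] <- 1.5
  # the causal tracks vary through their own gene-specific latents or
  # binding indicators rather than through the shared planted enhancer
  # state, so each planted signal is carried by exactly one feature column
  e_mult[c("H3K4me2", "H3K4me3", "IKAROS", "PU.1")] <- 1
  a_mult <- stats::setNames(rep(1, length(tracks)), tracks)
  a_mult[c("CTCF", "RAD21")] <- 10
  cfg <- list(
    n_genes = 162L,
    locus_length = 700000L,
    seed = 1L,
    n_replicates = 3L,
    n_events = 45000L,
    depth_multipliers = c(1, 1.25, 0.8),
    j_usage = c(J1 = 0.40, J2 = 0.25, J4 = 0.20, J5 = 0.15),
    chimaera_rate = 0.05,
    pcr_duplicate_rate = 0.3,
    unrecombined_fraction = 0.65,
    umi_length = 6L,
    anchor_sequences = c("ACGTACGTA", "TGCATGCAT"),
    read_length = 100L,
    bait_length = 20L,
    flank_length = 15L,
    junction_offsets = 0:14,
    reverse_fraction = 0.55,
    gene_length_range = c(400L, 650L),
    pseudogene_fraction = 0.4,
    n_families = 20L,
    ric_mixture = list(p_capable = 0.75, mean_capable = -12, sd_capable = 6,
                       mean_incapable = -45, sd_incapable = 4),
    ric_capability_threshold = -38.81,
    # PU.1 at the RSS acts as a near-binary switch: without it activation is
    # unlikely even for genes with a good RIC score
    activity_model = list(type = "logistic", intercept = -3.2,
                          beta_ric = 2.0, beta_pu1 = 6.0, beta_e_rss = 0.8),
    frequency_model = list(intercept = 10.5,
                           beta = c(ric = 1.2, H3K4me2_rss = 1.2,
                                    H3K4me3_rss = 1.2, IKAROS_rss = 1.2),
                           noise_sd = 0.5),
    p_pu1_bind = 0.7,
    # the enhancer state at the RSS co-occurs with PU.1 binding (PU.1 is an
    # enhancer-state factor), planting the state-activity association
    p_e_rss = 0.35,
    p_e_rss_given_pu1 = 0.75,
    p_e_prom = 0.5,
    p_a_upstream = 0.3,
    n_random_a_segments = 20L,
    plant_segments = TRUE,
    latent_effect = 1.2,
    pu1_bind_fold = 8,
    tracks = tracks,
    architectural_tracks = c("CTCF", "RAD21"),
    enhancer_tracks = enhancer,
    base_means = stats::setNames(rep(5, length(tracks)), tracks),
    e_multipliers = e_mult,
    a_multipliers = a_mult,
    nb_size = 20,
    bin_width = 200L,
    planted_duplications = NULL
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$umi_length == 6L,
            abs(sum(cfg$j_usage) - 1) < 1e-8,
            all(vapply(cfg[c("chimaera_rate", "pcr_duplicate_rate",
                             "unrecombined_fraction")], function(x)
              x >= 0 && x <= 1, logical(1))))
  structure(cfg, class = "kappa_config")
}

# substring() rejects zero-length index vectors; simulations at extreme
# configurations legitimately produce empty read sets
substring0 <- function(x, first, last) {
  if (length(first) == 0 || length(last) == 0) return(character(0))
  substring(x, first, last)
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Reverse complement of character sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate the locus: reference, annotations, J genes and per-gene truth
#'
#' Gene positions are non-overlapping with >=1.5 kb gaps; strands are drawn
#' with the configured reverse fraction; RIC scores come from a two-component
#' normal mixture so that a subset of genes falls below the capability
#' threshold. Per-gene chromatin indicators (enhancer state at promoter/RSS,
#' architectural segment upstream, PU.1 binding at the RSS) and continuous
#' per-feature enrichment latents are drawn here, then activity and log2
#' recombination frequency are generated from them, so chromatin simulation
#' and read simulation are conditionally deterministic on this truth.
#'
#' @param config a [sim_config()].
#' @return list of class `kappa_locus` with `reference`, `genes`, `jgenes`,
#'   `windows`, `truth`, `v_region_length`, `config`.
#' @export
simulate_locus <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  L <- config$locus_length
  j_region_start <- L - 12000L

  len <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                n, replace = TRUE)
  span_start <- 5000L
  span_end <- L - 25000L
  base_gap <- 1500L
  slack <- (span_end - span_start) - sum(len) - n * base_gap
  if (slack < 0) stop("locus too short for the requested number of genes")
  cuts <- sort(stats::runif(n))
  extra <- floor(diff(c(0, cuts)) * slack)
  gaps <- base_gap + extra
  start <- span_start + cumsum(gaps) + c(0L, cumsum(len))[seq_len(n)]
  end <- start + len
  # keep start+end even so the gene centre is exact under reflection
  end <- end + (start + end) %% 2L

  strand <- ifelse(stats::runif(n) < config$reverse_fraction, "-", "+")
  family <- paste0("Vk", sample.int(config$n_families, n, replace = TRUE))
  pseudogene <- stats::runif(n) < config$pseudogene_fraction

  mix <- config$ric_mixture
  capable <- stats::runif(n) < mix$p_capable
  ric <- ifelse(capable,
                stats::rnorm(n, mix$mean_capable, mix$sd_capable),
                stats::rnorm(n, mix$mean_incapable, mix$sd_incapable))

  # J genes near the 3' end of the locus; J3 is non-functional and absent
  j_ids <- c("J1", "J2", "J4", "J5")
  j_pos <- j_region_start + 400L * (seq_along(j_ids) - 1L)
  end3 <- ifelse(strand == "+", end, start)
  genes <- data.frame(id = sprintf("V%03d", seq_len(n)), start = start,
                      end = end, strand = strand, family = family,
                      pseudogene = pseudogene, ric_score = ric,
                      distance_to_j1 = abs(j_pos[1] - end3))

  reference <- random_dna(1, L)
  if (!is.null(config$planted_duplications)) {
    pd <- config$planted_duplications
    for (i in seq_len(nrow(pd))) {
      seg <- substring(reference, pd$src[i] + 1L, pd$src[i] + pd$len[i])
      substring(reference, pd$dest[i] + 1L, pd$dest[i] + pd$len[i]) <- seg
    }
  }

  baits <- random_dna(length(j_ids), config$bait_length)
  while (anyDuplicated(substring(baits, 1, 8))) {
    baits <- random_dna(length(j_ids), config$bait_length)
  }
  jgenes <- data.frame(id = j_ids, position = j_pos, bait = baits,
                       flank = substring(reference, j_pos + 1L,
                                         j_pos + config$flank_length))

  # latent chromatin indicators and continuous enrichment latents
  pu1_bind <- stats::runif(n) < config$p_pu1_bind
  e_rss <- stats::runif(n) <
    ifelse(pu1_bind, config$p_e_rss_given_pu1, config$p_e_rss)
  e_prom <- stats::runif(n) < config$p_e_prom
  a_up <- stats::runif(n) < config$p_a_upstream
  causal <- names(config$frequency_model$beta)
  chrom_causal <- setdiff(causal, "ric")
  u <- matrix(stats::rnorm(n * length(chrom_causal)), nrow = n,
              dimnames = list(genes$id, chrom_causal))

  # activity: logistic in RIC and PU.1-at-RSS (plus weak enhancer-state term),
  # or a hard RIC capability threshold
  am <- config$activity_model
  if (am$type == "threshold") {
    active <- ric > config$ric_capability_threshold
  } else {
    eta <- am$intercept + am$beta_ric * (ric + 20) / 10 +
      am$beta_pu1 * pu1_bind + am$beta_e_rss * e_rss
    active <- stats::runif(n) < stats::plogis(eta)
  }

  # log2 frequency: linear in the standardized gene-specific log2 enrichment
  # latents of the causal features (the latents multiply the corresponding
  # track counts over the gene's window, so the planted signal is carried by
  # exactly those feature columns) and in the RIC score
  fm <- config$frequency_model
  z <- matrix(0, nrow = n, ncol = length(causal),
              dimnames = list(genes$id, causal))
  # RIC standardized by the capable-component scale (recombination-capable
  # genes are the ones whose frequency the model describes); chromatin
  # latents are standard normal by construction
  if ("ric" %in% causal) z[, "ric"] <- (ric - mix$mean_capable) / mix$sd_capable
  for (cc in chrom_causal) z[, cc] <- u[, cc]
  log2_freq <- as.numeric(fm$intercept + z %*% fm$beta +
                            stats::rnorm(n, 0, fm$noise_sd))

  truth <- list(active = active, log2_freq = log2_freq, pu1_bind = pu1_bind,
                e_rss = e_rss, e_prom = e_prom, a_up = a_up, latents = u)
  windows <- gene_windows(genes, L)
  v_region_length <- (max(genes$end) + 500L) - (min(genes$start) - 500L)
  structure(list(reference = reference, genes = genes, jgenes = jgenes,
                 windows = windows, truth = truth,
                 v_region_length = v_region_length, config = config),
            class = "kappa_locus")
}

mark_bins <- function(state, a, b, label, bin_width, precedence) {
  if (b <= a) return(state)
  i0 <- max(0L, a %/% bin_width)
  i1 <- min(length(state) - 1L, (b - 1L) %/% bin_width)
  if (i1 < i0) return(state)
  idx <- (i0:i1) + 1L
  repl <- precedence[state[idx]] <= precedence[label]
  state[idx[repl]] <- label
  state
}

#' Simulate binned chromatin tracks and peak calls
#'
#' Plants Enhancer segments over the promoter/RSS windows and Architectural
#' segments ~2 kb upstream of genes according to the locus truth, plus random
#' intergenic Architectural segments, then draws per-200-bp-bin counts from
#' state- and gene-dependent negative binomials. Gene-local continuous
#' enrichment latents multiply the causal tracks over the RSS window, and
#' PU.1-bound genes get a strong PU.1 enrichment at the RSS. TF peak calls
#' (narrowPeak-style) are placed at the enriched windows.
#'
#' @param locus a [simulate_locus()] result.
#' @param config defaults to `locus$config`.
#' @return list with `tracks` (named list of data.frames `start`, `end`,
#'   `count`), `peaks` (named list of narrowPeak data.frames), `bin_states`
#'   (true per-bin state labels), `segments` (true A/E segments).
#' @export
simulate_chromatin <- function(locus, config = locus$config) {
  set.seed(config$seed + 1L)
  L <- config$locus_length
  bw <- config$bin_width
  n_bins <- L %/% bw
  genes <- locus$genes
  w <- locus$windows
  truth <- locus$truth
  precedence <- c(Bg = 0L, A = 1L, E = 2L)

  state <- rep("Bg", n_bins)
  segs <- list()
  if (isTRUE(config$plant_segments)) {
    for (g in seq_len(nrow(genes))) {
      fwd <- genes$strand[g] == "+"
      if (truth$a_up[g]) {
        a <- if (fwd) genes$start[g] - 2600L else genes$end[g] + 2000L
        segs[[length(segs) + 1L]] <- c(a, a + 600L, "A")
      }
      if (truth$e_prom[g]) {
        segs[[length(segs) + 1L]] <- c(w$promoter_start[g], w$promoter_end[g], "E")
      }
      if (truth$e_rss[g]) {
        segs[[length(segs) + 1L]] <- c(w$rss_start[g], w$rss_end[g], "E")
      }
    }
    near_gene <- function(p) any(p > genes$start - 3600L & p < genes$end + 3600L)
    tries <- 0L
    placed <- 0L
    while (placed < config$n_random_a_segments && tries < 2000L) {
      tries <- tries + 1L
      p <- floor(stats::runif(1, 5000, L - 20000))
      if (!near_gene(p)) {
        segs[[length(segs) + 1L]] <- c(p, p + 600L, "A")
        placed <- placed + 1L
      }
    }
    for (s in segs) {
      state <- mark_bins(state, as.integer(s[1]), as.integer(s[2]), s[3],
                         bw, precedence)
    }
  }

  bin_start <- (seq_len(n_bins) - 1L) * bw
  # bins fully inside [a, b): gene-local multipliers are confined to the
  # target window so the planted signal lands in exactly one feature column
  inner_bins <- function(a, b) {
    if (b <= a) return(integer(0))
    i0 <- max(0L, ceiling(a / bw))
    i1 <- min(n_bins, b %/% bw) - 1L
    if (i1 < i0) integer(0) else (i0:i1) + 1L
  }

  causal <- setdiff(names(config$frequency_model$beta), "ric")
  tracks <- list()
  for (tr in config$tracks) {
    mult <- rep(1, n_bins)
    mult[state == "A"] <- config$a_multipliers[tr]
    mult[state == "E"] <- config$e_multipliers[tr]
    for (cc in causal) {
      track <- sub("_(promoter|rss|upstream|downstream)$", "", cc)
      win <- sub("^.*_", "", cc)
      if (track == tr) {
        for (g in seq_len(nrow(genes))) {
          idx <- inner_bins(w[[paste0(win, "_start")]][g],
                            w[[paste0(win, "_end")]][g])
          mult[idx] <- mult[idx] *
            2^(config$latent_effect * truth$latents[g, cc])
        }
      }
    }
    if (tr == "PU.1") {
      for (g in which(truth$pu1_bind)) {
        idx <- inner_bins(w$rss_start[g], w$rss_end[g])
        mult[idx] <- mult[idx] * config$pu1_bind_fold
      }
    }
    mu <- config$base_means[tr] * mult
    counts <- stats::rnbinom(n_bins, size = config$nb_size, mu = mu)
    tracks[[tr]] <- data.frame(start = bin_start, end = bin_start + bw,
                               count = counts)
  }

  # peak calls at enriched windows (summit at the window midpoint)
  tf_tracks <- setdiff(config$tracks,
                       c("Nuclear_RNA", "H3K4me1", "H3K4me2", "H3K4me3",
                         "H3K9ac", "H3K27me3"))
  mid <- function(a, b) (a + b) %/% 2L
  peaks <- list()
  for (tr in tf_tracks) {
    summits <- integer(0)
    if (tr %in% config$architectural_tracks) {
      for (s in segs) if (s[3] == "A") {
        summits <- c(summits, mid(as.integer(s[1]), as.integer(s[2])))
      }
    } else {
      summits <- c(summits,
                   mid(w$promoter_start, w$promoter_end)[truth$e_prom],
                   mid(w$rss_start, w$rss_end)[truth$e_rss])
      if (tr == "PU.1") {
        summits <- c(summits, mid(w$rss_start, w$rss_end)[truth$pu1_bind])
      }
    }
    summits <- sort(unique(summits))
    if (length(summits) == 0) next
    peaks[[tr]] <- data.frame(
      chrom = "locus", start = pmax(0L, summits - 150L),
      end = pmin(L, summits + 150L),
      name = paste0(tr, "_peak", seq_along(summits)), score = 500L,
      strand = ".", signalValue = 10, pValue = 8, qValue = 5,
      peak = summits - pmax(0L, summits - 150L))
  }
  list(tracks = tracks, peaks = peaks, bin_states = state,
       segments = do.call(rbind, lapply(segs, function(s)
         data.frame(start = as.integer(s[1]), end = as.integer(s[2]),
                    label = s[3]))))
}

#' Simulate paired bait-capture reads with ground-truth labels
#'
#' Active genes emit events with multiplicity proportional to
#' `2^log2_frequency`. Read 1 is `UMI(6) + anchor(9) + 85 bp` of gene-strand
#' sequence sampled within the gene's 750-bp counting window; read 2 is
#' `bait(20) + J flank(15) + 65 bp` of V-derived junction sequence with a
#' random junctional offset. Chimaeras swap the bait for a wrong J's bait;
#' PCR duplicates re-emit identical records once with the configured
#' probability; unrecombined fragments carry germline sequence downstream of
#' the bait. Distinct parent molecules are guaranteed distinct on the
#' deduplication key (UMI, junction, alignment start) within each replicate.
#'
#' @param locus a [simulate_locus()] result.
#' @param config defaults to `locus$config`.
#' @return list with `read1`, `read2` (named character vectors) and `labels`
#'   (data.frame with one row per emitted read; `category` is exactly one of
#'   `event`, `duplicate`, `chimaera`, `unrecombined`).
#' @export
simulate_reads <- function(locus, config = locus$config) {
  set.seed(config$seed + 2L)
  genes <- locus$genes
  w <- locus$windows
  jg <- locus$jgenes
  truth <- locus$truth
  ref <- locus$reference
  k <- 85L
  jl_v <- config$read_length - config$bait_length - config$flank_length

  gseq <- substring(ref, genes$start + 1L, genes$end)
  gseq[genes$strand == "-"] <- revcomp(gseq[genes$strand == "-"])
  glen <- nchar(gseq)

  active_idx <- which(truth$active)
  weights <- 2^truth$log2_freq[active_idx]
  all_labels <- list()
  all_r1 <- list()
  all_r2 <- list()

  for (r in seq_len(config$n_replicates)) {
    n_ev <- round(config$n_events * config$depth_multipliers[r])
    if (length(active_idx) == 0) n_ev <- 0L
    gi <- if (n_ev > 0)
      sample(active_idx, n_ev, replace = TRUE, prob = weights) else integer(0)
    j <- sample(jg$id, n_ev, replace = TRUE, prob = config$j_usage[jg$id])
    off <- sample(config$junction_offsets, n_ev, replace = TRUE)
    cw_lo <- w$count_start[gi]
    cw_hi <- w$count_end[gi] - k
    v_start <- cw_lo + floor(stats::runif(n_ev) * (cw_hi - cw_lo + 1L))
    umi <- random_dna(n_ev, config$umi_length)
    # enforce distinct parent molecules on the dedup key
    key <- paste(j, umi, v_start, off)
    it <- 0L
    while (anyDuplicated(key) && it < 50L) {
      d <- duplicated(key)
      umi[d] <- random_dna(sum(d), config$umi_length)
      off[d] <- sample(config$junction_offsets, sum(d), replace = TRUE)
      key <- paste(j, umi, v_start, off)
      it <- it + 1L
    }

    vseq <- substring0(ref, v_start + 1L, v_start + k)
    neg <- genes$strand[gi] == "-"
    if (any(neg)) vseq[neg] <- revcomp(vseq[neg])
    anchor <- config$anchor_sequences[sample.int(2L, n_ev, replace = TRUE)]
    read1 <- paste0(umi, anchor, vseq)
    vjunc <- substring0(gseq[gi], glen[gi] - off - jl_v + 1L, glen[gi] - off)
    ji <- match(j, jg$id)
    junction <- paste0(jg$flank[ji], vjunc)
    read2 <- paste0(jg$bait[ji], junction)

    # unrecombined fragments: germline J-proximal sequence on both sides
    n_un <- round(n_ev * config$unrecombined_fraction /
                    (1 - config$unrecombined_fraction))
    if (n_ev == 0) {
      n_un <- round(config$n_events * config$depth_multipliers[r] *
                      config$unrecombined_fraction)
    }
    un_j <- sample(jg$id, n_un, replace = TRUE, prob = config$j_usage[jg$id])
    un_ji <- match(un_j, jg$id)
    un_region <- c(config$locus_length - 20000L, config$locus_length - 12100L)
    un_vstart <- un_region[1] +
      floor(stats::runif(n_un) * (un_region[2] - un_region[1] - k))
    un_umi <- random_dna(n_un, config$umi_length)
    un_anchor <- config$anchor_sequences[sample.int(2L, n_un, replace = TRUE)]
    un_r1 <- paste0(un_umi, un_anchor,
                    substring0(ref, un_vstart + 1L, un_vstart + k))
    un_r2 <- paste0(jg$bait[un_ji],
                    substring0(ref, jg$position[un_ji] + 1L,
                               jg$position[un_ji] + config$flank_length + jl_v))

    lab <- data.frame(
      replicate = r,
      gene = c(genes$id[gi], rep(NA_character_, n_un)),
      j = c(j, un_j),
      true_j = c(j, un_j),
      umi = c(umi, un_umi),
      v_start = c(v_start, un_vstart),
      v_strand = c(genes$strand[gi], rep("+", n_un)),
      offset = c(off, rep(NA_integer_, n_un)),
      unrecombined = c(rep(FALSE, n_ev), rep(TRUE, n_un)))
    r1 <- c(read1, un_r1)
    r2 <- c(read2, un_r2)

    # chimaeras: wrong J's bait in front of the correct downstream flank
    chim <- stats::runif(nrow(lab)) < config$chimaera_rate
    if (any(chim)) {
      wrong <- vapply(lab$true_j[chim], function(x)
        sample(setdiff(jg$id, x), 1L), character(1))
      r2[chim] <- paste0(jg$bait[match(wrong, jg$id)],
                         substring(r2[chim], config$bait_length + 1L))
      lab$j[chim] <- wrong
    }
    lab$chimaera <- chim

    # one Bernoulli re-emission per molecule
    dup <- stats::runif(nrow(lab)) < config$pcr_duplicate_rate
    lab$parent <- seq_len(nrow(lab))
    if (any(dup)) {
      lab2 <- lab[dup, ]
      lab <- rbind(lab, lab2)
      r1 <- c(r1, r1[dup])
      r2 <- c(r2, r2[dup])
      lab$duplicate <- c(rep(FALSE, sum(!duplicated(lab$parent))),
                         rep(TRUE, sum(dup)))
    } else {
      lab$duplicate <- FALSE
    }
    ord <- sample.int(nrow(lab))
    lab <- lab[ord, ]
    r1 <- r1[ord]
    r2 <- r2[ord]
    lab$read_id <- sprintf("r%d_%06d", r, seq_len(nrow(lab)))
    lab$category <- ifelse(lab$duplicate, "duplicate",
                           ifelse(lab$chimaera, "chimaera",
                                  ifelse(lab$unrecombined, "unrecombined",
                                         "event")))
    names(r1) <- lab$read_id
    names(r2) <- lab$read_id
    all_labels[[r]] <- lab
    all_r1[[r]] <- r1
    all_r2[[r]] <- r2
  }
  labels <- do.call(rbind, all_labels)
  rownames(labels) <- NULL
  list(read1 = unlist(all_r1), read2 = unlist(all_r2), labels = labels)
}

#' Simulate binned tracks from a known hidden state path
#'
#' Draws a Markov state path and per-bin negative-binomial counts from the
#' given per-state per-track means; used to test segmentation recovery.
#'
#' @param means K x T matrix of per-state per-track means.
#' @param trans K x K transition matrix (rows sum to 1).
#' @param n_bins number of bins.
#' @param size negative-binomial size (dispersion) parameter.
#' @param seed RNG seed.
#' @return list with `X` (T x n_bins count matrix) and `states` (true path).
#' @export
simulate_state_tracks <- function(means, trans, n_bins, size = 10, seed = 1) {
  set.seed(seed)
  K <- nrow(means)
  states <- integer(n_bins)
  states[1] <- sample.int(K, 1)
  for (j in 2:n_bins) {
    states[j] <- sample.int(K, 1, prob = trans[states[j - 1], ])
  }
  X <- t(vapply(seq_len(ncol(means)), function(i)
    stats::rnbinom(n_bins, size = size, mu = means[states, i]),
    numeric(n_bins)))
  rownames(X) <- colnames(means)
  list(X = X, states = states)
}

#' Write paired reads as FASTQ
#' @param reads character vector of sequences (names become read ids).
#' @param file output path.
#' @export
write_fastq <- function(reads, file) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(dna), function(wd)
    strrep("I", wd), character(1)))
  Biostrings::writeXStringSet(dna, file, format = "fastq", qualities = qual)
  invisible(file)
}

#' Read a FASTQ file as a named character vector
#' @param file FASTQ path.
#' @export
read_fastq <- function(file) {
  dna <- Biostrings::readDNAStringSet(file, format = "fastq")
  stats::setNames(as.character(dna), names(dna))
}

#' Write peak calls in narrowPeak format
#' @param peaks a peak data.frame as produced by [simulate_chromatin()].
#' @param file output path.
#' @export
write_narrowpeak <- function(peaks, file) {
  utils::write.table(peaks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a binned track as bedGraph
#' @param track data.frame with `start`, `end`, `count`.
#' @param file output path.
#' @export
write_bedgraph <- function(track, file) {
  utils::write.table(data.frame("locus", track$start, track$end, track$count),
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
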