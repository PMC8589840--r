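#' Simulation parameters for RTG recombination
#'
#' Bundles the tunable parameters of the return-to-growth (RTG) recombination
#' mechanism. A meiotic cell replicates each homolog into two sister
#' chromatids (four chromatids per chromosome pair), Spo11 cuts the genome at
#' Poisson-many positions (preferentially inside recombination hotspots, and
#' never near centromeres), each repaired break resolves either as a
#' reciprocal crossover (CO) or a one-way gene-conversion tract (NCO), and the
#' aborted-meiosis cell then buds mitotically, segregating chromatids 2+2 into
#' a mother and a daughter with no further replication. Sequence divergence
#' suppresses recombination through mismatch-repair anti-recombination: each
#' heteroduplex mismatch in the repair tract independently rejects the event
#' with probability `rho`; the `msh2_null` switch disables this surveillance.
#'
#' @param lambda Mean number of DSBs per cell per aborted meiosis (Poisson).
#' @param hotspot_weight Probability that a DSB falls inside a hotspot
#'   interval (with probability proportional to the hit count `H`); the
#'   remainder fall uniformly on the unsuppressed genome. Ignored when no
#'   hotspot track is supplied.
#' @param cen_radius Pericentromeric suppression radius (bp): no DSB is
#'   placed within this distance of a centromere, and conversion tracts are
#'   directed away from the centromere, so pericentromeric markers stay
#'   heterozygous.
#' @param p_co Probability that a surviving DSB resolves as a crossover
#'   (otherwise: non-crossover conversion).
#' @param tract_mean Mean conversion/repair tract length in bp (geometric).
#' @param rho Per-mismatch probability that the mismatch-repair machinery
#'   aborts the recombination event; the event survives with probability
#'   `(1 - rho)^m` for `m` markers in the repair tract.
#' @param msh2_null If `TRUE`, model an msh2-deletion background: `rho` is
#'   forced to 0 and heteroduplex rejection is off.
#' @param missing_rate Per-marker probability of an uncalled (`MISSING`)
#'   genotype in the emitted tracks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(lambda = 20, hotspot_weight = 0.8, cen_radius = 20000,
                       p_co = 0.3, tract_mean = 2000, rho = 0.1,
                       msh2_null = FALSE, missing_rate = 0) {
  stopifnot(lambda >= 0, p_co >= 0, p_co <= 1, rho >= 0, rho <= 1,
            tract_mean > 0, cen_radius >= 0,
            hotspot_weight >= 0, hotspot_weight <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(lambda = lambda, hotspot_weight = hotspot_weight,
                 cen_radius = cen_radius, p_co = p_co,
                 tract_mean = tract_mean, rho = rho, msh2_null = msh2_null,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate a marker map at a given divergence
#'
#' Marker positions are drawn as a per-bp Bernoulli process with
#' heterozygosity `theta` (the fraction of sites differing between the two
#' parental subgenomes), so a chromosome of length L carries
#' Binomial(L, theta) markers. Alleles are arbitrary distinct nucleotides.
#' Subtelomeric masks from the layout are applied.
#'
#' @param layout A [genome_layout()].
#' @param theta Per-bp marker density in `[0, 0.2]`.
#' @param seed Optional integer seed.
#' @return A [marker_map()] with `masked` set.
#' @export
simulate_marker_map <- function(layout, theta, seed = NULL) {
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (theta > 0.2) stop("theta must be <= 0.2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    n <- stats::rbinom(1, len, theta)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n))
    a1 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
    tibble::tibble(chrom = layout$chrom[i], pos = pos, allele1 = a1,
                   allele2 = unname(a2))
  })
  df <- dplyr::bind_rows(pieces)
  if (nrow(df) == 0) {
    return(marker_map(tibble::tibble(chrom = character(), pos = numeric(),
                                     allele1 = character(),
                                     allele2 = character())))
  }
  apply_masks(marker_map(df), layout)
}

#' Simulate a recombination hotspot track
#'
#' Places `n_per_chrom` non-overlapping hotspot intervals per chromosome,
#' uniformly outside the pericentromeric suppression zone, with interval
#' widths geometric around `width_mean` and log-normal intensity hits.
#'
#' @param layout A [genome_layout()].
#' @param n_per_chrom Hotspots per chromosome.
#' @param width_mean Mean hotspot width (bp).
#' @param cen_radius Zone around centromeres kept hotspot-free (bp).
#' @param seed Optional seed.
#' @return An [interval_track()] with intensity `hits`.
#' @export
simulate_hotspots <- function(layout, n_per_chrom = 40, width_mean = 500,
                              cen_radius = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    lo <- max(1, layout$cen_start[i] - cen_radius)
    hi <- min(len, layout$cen_end[i] + cen_radius)
    w <- pmax(50, stats::rgeom(n_per_chrom, 1 / width_mean))
    # draw starts on the two arms, proportionally to arm length
    arm_len <- c(max(0, lo - 1), max(0, len - hi))
    arm <- sample(1:2, n_per_chrom, replace = TRUE, prob = arm_len)
    start <- ifelse(arm == 1,
                    floor(stats::runif(n_per_chrom, 1, pmax(2, lo - w))),
                    floor(stats::runif(n_per_chrom, hi + 1, pmax(hi + 2, len - w))))
    tibble::tibble(chrom = layout$chrom[i], start = start,
                   end = pmin(start + w - 1, len),
                   hits = round(stats::rlnorm(n_per_chrom, log(50), 1)) + 1)
  })
  df <- dplyr::bind_rows(pieces)
  interval_track(df$chrom, df$start, df$end, df$hits)
}

# ---- internal: DSB placement ---------------------------------------------

# Allowed (unsuppressed) arm regions per chromosome. Returns a data.frame
# with one row per arm: chrom, lo, hi, width, arm ("L"/"R").
allowed_regions <- function(layout, cen_radius) {
  res <- lapply(seq_len(nrow(layout)), function(i) {
    lo_l <- 1
    hi_l <- layout$cen_start[i] - cen_radius - 1
    lo_r <- layout$cen_end[i] + cen_radius + 1
    hi_r <- layout$length[i]
    out <- data.frame(chrom = layout$chrom[i],
                      lo = c(lo_l, lo_r), hi = c(hi_l, hi_r),
                      arm = c("L", "R"))
    out$width <- pmax(0, out$hi - out$lo + 1)
    out[out$width > 0, , drop = FALSE]
  })
  do.call(rbind, res)
}

in_suppressed <- function(layout, chrom, pos, cen_radius) {
  i <- layout_row(layout, chrom)
  pos >= layout$cen_start[i] - cen_radius & pos <= layout$cen_end[i] + cen_radius
}

draw_dsb_positions <- function(n, layout, hotspots, config) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric()))
  }
  regions <- allowed_regions(layout, config$cen_radius)
  has_hs <- !is.null(hotspots) && nrow(hotspots) > 0
  chrom <- character(n)
  pos <- numeric(n)
  for (k in seq_len(n)) {
    use_hs <- has_hs && stats::runif(1) < config$hotspot_weight
    ok <- FALSE
    if (use_hs) {
      for (try in 1:100) {
        j <- sample.int(nrow(hotspots), 1, prob = hotspots$hits + 1e-9)
        p <- floor(stats::runif(1, hotspots$start[j], hotspots$end[j] + 1))
        if (!in_suppressed(layout, hotspots$chrom[j], p, config$cen_radius) &&
            p >= 1 && p <= layout$length[layout_row(layout, hotspots$chrom[j])]) {
          chrom[k] <- hotspots$chrom[j]; pos[k] <- p; ok <- TRUE; break
        }
      }
    }
    if (!ok) {
      j <- sample.int(nrow(regions), 1, prob = regions$width)
      chrom[k] <- regions$chrom[j]
      pos[k] <- floor(stats::runif(1, regions$lo[j], regions$hi[j] + 1))
    }
  }
  tibble::tibble(chrom = chrom, pos = pos)
}

# ---- internal: chromatid state and genotyping ----------------------------

genotype_from_chromatids <- function(p, q) {
  out <- rep("HET", length(p))
  hom <- p == q
  out[hom & p == 1] <- "HOM_P1"
  out[hom & p == 2] <- "HOM_P2"
  out
}

# Maximal homozygous runs for one cell on one chromosome, non-masked markers
# only; class by the arm-end rule (reaches the first/last non-masked marker).
state_runs <- function(geno, pos, masked) {
  keep <- !masked
  g <- geno[keep]; p <- pos[keep]
  m <- length(g)
  if (m == 0) return(NULL)
  code <- integer(m)
  code[g == "HOM_P1"] <- 1L
  code[g == "HOM_P2"] <- 2L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hom <- r$values > 0
  if (!any(hom)) return(NULL)
  i1 <- starts[hom]; i2 <- ends[hom]
  cls <- ifelse(i1 == 1 & i2 == m, "whole_chromosome",
                ifelse(i1 == 1 | i2 == m, "terminal", "interstitial"))
  tibble::tibble(parent = c("P1", "P2")[r$values[hom]],
                 first = p[i1], last = p[i2],
                 n_markers = i2 - i1 + 1, class = cls)
}

#' Simulate one RTG mother/daughter genotype pair
#'
#' Implements the RTG mechanism on four chromatids per chromosome: DSBs are
#' drawn from Poisson(`lambda`), placed hotspot-weighted with pericentromeric
#' suppression, thinned by mismatch-repair anti-recombination, and resolved
#' as crossovers (reciprocal exchange of everything distal to the break
#' between one chromatid of each parent) or as one-way conversion tracts of
#' geometric length directed away from the centromere. Chromatids then
#' segregate 2+2, each cell keeping one centromere of each homolog, and both
#' cells are genotyped at every marker.
#'
#' The returned ground truth carries every DSB (including events rejected by
#' anti-recombination), the expected LOH segments of both cells (maximal
#' homozygous runs over non-masked markers, classified by the arm-end rule),
#' and the markers at which allele dosage across the pair deviates from
#' 2:2 (the non-reciprocal footprint of conversions).
#'
#' @param map A [marker_map()] (ideally with masks applied).
#' @param layout A [genome_layout()].
#' @param hotspots Optional [interval_track()] of recombination hotspots.
#' @param config A [sim_config()].
#' @param pair_id Prefix for the two clone identifiers.
#' @param seed Optional seed.
#' @return A list of class `rtg_pair` with elements `mother` and `daughter`
#'   (genotype tibbles: `clone`, `chrom`, `pos`, `genotype`), `events`,
#'   `truth_segments` (columns `clone`, `chrom`, `parent`, `first`, `last`,
#'   `n_markers`, `class`) and `nonreciprocal` (tibble of `chrom`, `pos`).
#' @export
simulate_rtg_pair <- function(map, layout, hotspots = NULL,
                              config = sim_config(), pair_id = "pair1",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(map) == 0 && config$lambda > 0) {
    stop("cannot simulate recombination on an empty marker map", call. = FALSE)
  }
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    layout_row(layout, unique(hotspots$chrom))  # errors on unknown chromosome
  }
  chroms <- layout$chrom
  map_idx <- split(seq_len(nrow(map)), factor(map$chrom, levels = chroms))
  pos_by <- lapply(map_idx, function(i) map$pos[i])
  # chromatid state: 4 x m parent matrix; rows 1:2 carry the P1 centromere,
  # rows 3:4 the P2 centromere (identity = centromere, COs never cross it)
  state <- lapply(pos_by, function(p) {
    matrix(rep(c(1L, 1L, 2L, 2L), length(p)), nrow = 4)
  })
  names(state) <- chroms

  n_dsb <- stats::rpois(1, config$lambda)
  dsb <- draw_dsb_positions(n_dsb, layout, hotspots, config)
  rho <- if (config$msh2_null) 0 else config$rho
  ev <- vector("list", nrow(dsb))
  for (k in seq_len(nrow(dsb))) {
    ch <- dsb$chrom[k]; p <- dsb$pos[k]
    li <- layout_row(layout, ch)
    arm <- if (p < layout$cen_start[li]) "L" else "R"
    len <- layout$length[li]
    broken <- sample.int(4, 1)
    donor <- if (broken <= 2) sample(3:4, 1) else sample(1:2, 1)
    tl <- stats::rgeom(1, 1 / config$tract_mean) + 1
    if (arm == "R") {
      ts <- p; te <- min(p + tl - 1, len)
    } else {
      ts <- max(p - tl + 1, 1); te <- p
    }
    mpos <- pos_by[[ch]]
    tract_idx <- which(mpos >= ts & mpos <= te)
    m <- length(tract_idx)
    aborted <- stats::runif(1) > (1 - rho)^m
    type <- NA_character_
    if (!aborted) {
      is_co <- stats::runif(1) < config$p_co
      type <- if (is_co) "CO" else "NCO"
      st <- state[[ch]]
      if (is_co) {
        idx <- if (arm == "R") which(mpos > p) else which(mpos < p)
        if (length(idx) > 0) {
          tmp <- st[broken, idx]
          st[broken, idx] <- st[donor, idx]
          st[donor, idx] <- tmp
        }
      } else if (m > 0) {
        st[broken, tract_idx] <- st[donor, tract_idx]
      }
      state[[ch]] <- st
    }
    ev[[k]] <- tibble::tibble(chrom = ch, pos = p, arm = arm, type = type,
                              chromatid_broken = broken,
                              chromatid_donor = donor,
                              tract_start = ts, tract_end = te,
                              mismatches = m, aborted = aborted)
  }
  events <- if (length(ev) > 0) dplyr::bind_rows(ev) else
    tibble::tibble(chrom = character(), pos = numeric(), arm = character(),
                   type = character(), chromatid_broken = integer(),
                   chromatid_donor = integer(), tract_start = numeric(),
                   tract_end = numeric(), mismatches = integer(),
                   aborted = logical())

  # mitotic-like 2+2 segregation: the mother keeps one centromere of each
  # homolog per chromosome, independently across chromosomes
  mo_calls <- list(); da_calls <- list(); truth <- list(); nonrec <- list()
  for (ch in chroms) {
    mpos <- pos_by[[ch]]
    if (length(mpos) == 0) next
    st <- state[[ch]]
    a <- sample(1:2, 1); b <- sample(3:4, 1)
    mo <- genotype_from_chromatids(st[a, ], st[b, ])
    da <- genotype_from_chromatids(st[setdiff(1:2, a), ], st[setdiff(3:4, b), ])
    mo_calls[[ch]] <- mo; da_calls[[ch]] <- da
    masked <- map$masked[map_idx[[ch]]]
    tm <- state_runs(mo, mpos, masked)
    td <- state_runs(da, mpos, masked)
    if (!is.null(tm)) truth[[paste0(ch, ".m")]] <- dplyr::mutate(
      tm, clone = paste0(pair_id, "_mother"), chrom = ch, .before = 1)
    if (!is.null(td)) truth[[paste0(ch, ".d")]] <- dplyr::mutate(
      td, clone = paste0(pair_id, "_daughter"), chrom = ch, .before = 1)
    dosage <- colSums(st == 1L)
    bad <- which(dosage != 2)
    if (length(bad) > 0) {
      nonrec[[ch]] <- tibble::tibble(chrom = ch, pos = mpos[bad])
    }
  }

  make_track <- function(calls, clone) {
    g <- unlist(calls, use.names = FALSE)
    out <- tibble::tibble(
      clone = clone,
      chrom = rep(chroms, times = vapply(pos_by, length, 0L)),
      pos = unlist(pos_by, use.names = FALSE),
      genotype = g
    )
    if (config$missing_rate > 0) {
      drop <- stats::runif(nrow(out)) < config$missing_rate
      out$genotype[drop] <- "MISSING"
    }
    out
  }
  structure(list(
    mother = make_track(mo_calls, paste0(pair_id, "_mother")),
    daughter = make_track(da_calls, paste0(pair_id, "_daughter")),
    events = events,
    truth_segments = if (length(truth) > 0) dplyr::bind_rows(truth) else
      tibble::tibble(clone = character(), chrom = character(),
                     parent = character(), first = numeric(), last = numeric(),
                     n_markers = integer(), class = character()),
    nonreciprocal = if (length(nonrec) > 0) dplyr::bind_rows(nonrec) else
      tibble::tibble(chrom = character(), pos = numeric())
  ), class = "rtg_pair")
}

#' Simulate a population of RTG pairs
#'
#' Runs [simulate_rtg_pair()] `n_pairs` times with per-pair seeds derived
#' from `seed`, so any pair can be regenerated independently of the rest.
#'
#' @inheritParams simulate_rtg_pair
#' @param n_pairs Number of mother/daughter pairs.
#' @param seed Integer seed for the whole population.
#' @return A list with `genotypes` (all clones stacked), `events`,
#'   `truth_segments`, `nonreciprocal` (with a `pair` column) and `pairs`
#'   (the individual `rtg_pair` objects).
#' @export
simulate_rtg_population <- function(map, layout, hotspots = NULL,
                                    config = sim_config(), n_pairs = 10,
                                    seed = 1) {
  pairs <- lapply(seq_len(n_pairs), function(i) {
    id <- sprintf("pair%03d", i)
    p <- simulate_rtg_pair(map, layout, hotspots, config, pair_id = id,
                           seed = (seed + i * 9973L) %% .Machine$integer.max)
    p$pair <- id
    p
  })
  list(
    genotypes = dplyr::bind_rows(lapply(pairs, function(p)
      dplyr::bind_rows(p$mother, p$daughter))),
    events = dplyr::bind_rows(lapply(pairs, function(p)
      dplyr::mutate(p$events, pair = p$pair, .before = 1))),
    truth_segments = dplyr::bind_rows(lapply(pairs, function(p)
      dplyr::mutate(p$truth_segments, pair = p$pair, .before = 1))),
    nonreciprocal = dplyr::bind_rows(lapply(pairs, function(p)
      dplyr::mutate(p$nonreciprocal, pair = p$pair, .before = 1))),
    pairs = pairs
  )
}

#' Simulate a mitotic (T0 control) genotype track
#'
#' Background mitotic LOH: event count ~ Poisson(`rate * generations`),
#' events placed uniformly on the genome with tract lengths from the same
#' geometric distribution as conversion tracts, each converting its markers
#' to a random parent.
#'
#' @param map A [marker_map()].
#' @param layout A [genome_layout()].
#' @param rate Expected LOH events per genome per division.
#' @param generations Number of divisions.
#' @param tract_mean Mean tract length (bp).
#' @param clone Clone identifier.
#' @param seed Optional seed.
#' @return A genotype tibble (`clone`, `chrom`, `pos`, `genotype`).
#' @export
simulate_mitotic_track <- function(map, layout, rate, generations = 1,
                                   tract_mean = 2000, clone = "T0",
                                   seed = NULL) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::tibble(clone = clone, chrom = map$chrom, pos = map$pos,
                        genotype = rep("HET", nrow(map)))
  n_ev <- stats::rpois(1, rate * generations)
  for (k in seq_len(n_ev)) {
    i <- sample.int(nrow(layout), 1, prob = layout$length)
    ch <- layout$chrom[i]
    p <- floor(stats::runif(1, 1, layout$length[i] + 1))
    tl <- stats::rgeom(1, 1 / tract_mean) + 1
    parent <- sample(c("HOM_P1", "HOM_P2"), 1)
    hit <- out$chrom == ch & out$pos >= p & out$pos <= p + tl - 1
    out$genotype[hit] <- parent
  }
  out
}

#' Simulate clone phenotypes with planted QTLs
#'
#' Each clone's phenotype is the sum of QTL effects over its genotypes at the
#' QTL markers plus Gaussian noise: a QTL contributes its `effect` when the
#' clone is homozygous for the stated `parent` at that marker, and 0
#' otherwise.
#'
#' @param genotypes Long genotype tibble (`clone`, `chrom`, `pos`,
#'   `genotype`) covering all clones.
#' @param qtl Tibble with columns `chrom`, `pos`, `effect`, `parent`
#'   (`"P1"` or `"P2"`); may have zero rows.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param environment Label for the environment column.
#' @param seed Optional seed.
#' @return A tibble (`clone`, `environment`, `phenotype`).
#' @export
simulate_phenotypes <- function(genotypes, qtl, noise_sd = 0,
                                environment = "env1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clones <- unique(genotypes$clone)
  base <- stats::setNames(rep(0, length(clones)), clones)
  if (nrow(qtl) > 0) {
    for (k in seq_len(nrow(qtl))) {
      at <- genotypes[genotypes$chrom == qtl$chrom[k] &
                        genotypes$pos == qtl$pos[k], ]
      if (nrow(at) == 0) {
        stop(sprintf("QTL marker %s:%s not present in the genotypes",
                     qtl$chrom[k],
                     format(qtl$pos[k], scientific = FALSE)), call. = FALSE)
      }
      hom <- paste0("HOM_", qtl$parent[k])
      hit <- at$clone[at$genotype == hom]
      base[hit] <- base[hit] + qtl$effect[k]
    }
  }
  tibble::tibble(clone = clones, environment = environment,
                 phenotype = unname(base) +
                   stats::rnorm(length(clones), 0, noise_sd))
}
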