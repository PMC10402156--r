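#' Synthetic dataset configuration
#'
#' The generator plants a stated world mirroring the method's core premise:
#' sparse binary single-cell accessibility with cluster structure, loop
#' anchors whose accessibility is coupled within a cell (driving Jaccard
#' co-accessibility), and a distance-decaying contact map enriched at the
#' planted anchors. Defaults: one 5 Mb chromosome, 800 cells in 2 clusters,
#' 30 loops with anchors 50 kb - 2 Mb apart, background open rate 0.02 per
#' 500bp bin, anchor marginal rate 0.25, loop latent on-probability 0.4,
#' joint-opening coupling 0.8, contact decay `mu(d) = A / (d_bins + d0_bins)`
#' with A = 100 and d0 = 10 kb (one bin), 5-fold contact enhancement at loop
#' anchors, Poisson counts.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_cells number of cells.
#' @param n_clusters number of cell clusters (loops are split disjointly
#'   across clusters).
#' @param n_loops planted loops per chromosome.
#' @param loop_distance_range anchor distance range in bp.
#' @param p_anchor anchor open probability when the loop latent is off (or
#'   on but uncoupled).
#' @param p_bg background bin open probability.
#' @param theta loop latent on-probability per cell.
#' @param coupling probability that both anchors open jointly given the
#'   latent is on.
#' @param decay_A,decay_d0,decay_alpha distance-decay `A * (d + d0)^-alpha`
#'   (d in bins; d0 in bp, converted).
#' @param loop_enhancement contact enhancement factor at loop anchors (beta).
#' @param nb_dispersion optional negative-binomial size parameter; NULL =
#'   Poisson counts.
#' @param resolution contact-map resolution (bp).
#' @param coacc_resolution accessibility bin size (bp).
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chrS = 5e6), n_cells = 800L,
                       n_clusters = 2L, n_loops = 30L,
                       loop_distance_range = c(5e4, 2e6),
                       p_anchor = 0.25, p_bg = 0.02, theta = 0.4,
                       coupling = 0.8, decay_A = 100, decay_d0 = 1e4,
                       decay_alpha = 1, loop_enhancement = 5,
                       nb_dispersion = NULL, resolution = 1e4,
                       coacc_resolution = 500L) {
  stopifnot(all(c(p_anchor, p_bg, theta, coupling) >= 0),
            all(c(p_anchor, p_bg, theta, coupling) <= 1),
            loop_distance_range[1] >= resolution)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the genome scaffold: loops and cluster assignments
#'
#' Places `n_loops` loop anchors per chromosome on contact bins with
#' anchor distance uniform in `loop_distance_range`, assigns each loop to a
#' cluster (disjoint sets, round-robin) and each cell to a cluster
#' (uniform). Each anchor also gets one designated 500bp site (the central
#' accessibility bin of the anchor).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `layout`, `loops` (data.table: chrom, bin1, bin2,
#'   site1, site2, cluster), `cell_clusters`, `config`.
#' @export
simulate_genome <- function(config, seed = 1L) {
  layout <- genome_layout(names(config$chrom_lengths), config$chrom_lengths)
  withr_seed(seed, {
    max_len <- max(config$chrom_lengths)
    loops <- data.table::rbindlist(lapply(layout$chrom_names, function(cn) {
      n_bins <- bin_count(layout, cn, config$resolution)
      # n_loops loops on the longest chromosome, proportional elsewhere
      n_target <- max(1L, as.integer(round(config$n_loops *
                                           chrom_length(layout, cn) / max_len)))
      dr <- pmin(config$loop_distance_range,
                 (n_bins - 2L) * config$resolution)
      d_min <- as.integer(ceiling(dr[1] / config$resolution))
      d_max <- as.integer(floor(dr[2] / config$resolution))
      got <- 0L; tries <- 0L
      rows <- list()
      used <- character()
      while (got < n_target && tries < n_target * 50L) {
        tries <- tries + 1L
        d <- sample(d_min:d_max, 1L)
        b1 <- sample.int(n_bins - d, 1L)
        key <- paste(b1, b1 + d)
        if (key %in% used) next
        used <- c(used, key)
        got <- got + 1L
        rows[[got]] <- data.table::data.table(chrom = cn, bin1 = b1,
                                              bin2 = b1 + d)
      }
      if (got < n_target)
        stop("could not place ", n_target, " distinct loops on ", cn)
      data.table::rbindlist(rows)
    }))
    loops$cluster <- rep_len(seq_len(config$n_clusters), nrow(loops))
    fpb <- config$resolution %/% config$coacc_resolution
    loops$site1 <- (loops$bin1 - 1L) * fpb + fpb %/% 2L + 1L
    loops$site2 <- (loops$bin2 - 1L) * fpb + fpb %/% 2L + 1L
    cell_clusters <- sample(rep_len(seq_len(config$n_clusters),
                                    config$n_cells))
    list(layout = layout, loops = loops, cell_clusters = cell_clusters,
         config = config)
  })
}

#' Simulate single-cell accessibility and fragments
#'
#' Per cell: background 500bp bins open independently with `p_bg`; for each
#' loop of the cell's cluster a latent "loop on" draw (`theta`) makes both
#' anchor sites open jointly with probability `coupling`, otherwise the
#' sites open independently with `p_anchor`. One fragment is synthesized
#' inside every open bin, so fragment endpoints (Tn5 insertions) land in the
#' open bins.
#'
#' @param sim result of [simulate_genome()].
#' @param seed RNG seed.
#' @return list with `fragments` (data.table) and `cell_bins` (named list of
#'   binary cells x 500bp-bin matrices per chromosome), `barcodes`.
#' @export
simulate_scatac <- function(sim, seed = 2L) {
  cfg <- sim$config
  barcodes <- sprintf("cell_%04d", seq_len(cfg$n_cells))
  withr_seed(seed, {
    frag_list <- list()
    cell_bins <- list()
    for (cn in sim$layout$chrom_names) {
      nb <- bin_count(sim$layout, cn, cfg$coacc_resolution)
      loops <- sim$loops[sim$loops$chrom == cn, ]
      ii <- list(); jj <- list()
      for (c_idx in seq_len(cfg$n_cells)) {
        n_open <- stats::rbinom(1L, nb, cfg$p_bg)
        open <- if (n_open > 0) sample.int(nb, n_open) else integer()
        cl_loops <- loops[loops$cluster == sim$cell_clusters[c_idx], ]
        if (nrow(cl_loops)) {
          on <- stats::runif(nrow(cl_loops)) < cfg$theta
          joint <- on & (stats::runif(nrow(cl_loops)) < cfg$coupling)
          open <- c(open, cl_loops$site1[joint], cl_loops$site2[joint])
          solo <- which(!joint)
          if (length(solo)) {
            s1 <- stats::runif(length(solo)) < cfg$p_anchor
            s2 <- stats::runif(length(solo)) < cfg$p_anchor
            open <- c(open, cl_loops$site1[solo[s1]],
                      cl_loops$site2[solo[s2]])
          }
        }
        open <- unique(open)
        if (length(open)) {
          ii[[c_idx]] <- rep(c_idx, length(open)); jj[[c_idx]] <- open
        }
      }
      i <- unlist(ii); j <- unlist(jj)
      cell_bins[[cn]] <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                              dims = c(cfg$n_cells, nb))
      # one fragment inside each open bin; both endpoints stay inside it
      bin_start <- (j - 1L) * cfg$coacc_resolution
      off <- sample.int(cfg$coacc_resolution %/% 2L, length(j),
                        replace = TRUE) - 1L
      flen <- sample(50:200, length(j), replace = TRUE)
      fend <- pmin(bin_start + off + flen,
                   bin_start + cfg$coacc_resolution)
      frag_list[[cn]] <- data.table::data.table(
        chrom = cn, start = bin_start + off, end = fend,
        barcode = barcodes[i], count = 1L)
    }
    fragments <- data.table::rbindlist(frag_list)
    data.table::setorderv(fragments, c("chrom", "start"))
    list(fragments = fragments, cell_bins = cell_bins, barcodes = barcodes)
  })
}

# expected contact count at bin distance d (d in bins)
sim_decay <- function(cfg, d_bins) {
  d0 <- cfg$decay_d0 / cfg$resolution
  cfg$decay_A * (d_bins + d0)^(-cfg$decay_alpha)
}

#' Simulate a contact map as a cluster mixture
#'
#' Expected count `e(i, j) = mu(|i - j|) * (1 + (beta - 1) * sum_k w_k *
#' planted_k(i, j))` with Poisson (or negative binomial) noise; bulk maps
#' use the cluster proportions as weights, cluster maps a single unit
#' weight.
#'
#' @param sim result of [simulate_genome()].
#' @param cluster_weights numeric weights summing to 1 (length n_clusters).
#' @param seed RNG seed.
#' @param max_distance cap on simulated pair distance in bp (default 2e6).
#' @return named list of [contact_map()]s per chromosome.
#' @export
simulate_contacts <- function(sim, cluster_weights, seed = 3L,
                              max_distance = 2e6) {
  cfg <- sim$config
  stopifnot(abs(sum(cluster_weights) - 1) < 1e-8,
            length(cluster_weights) == cfg$n_clusters)
  withr_seed(seed, {
    maps <- lapply(sim$layout$chrom_names, function(cn) {
      n <- bin_count(sim$layout, cn, cfg$resolution)
      max_d <- min(as.integer(max_distance %/% cfg$resolution), n - 1L)
      loops <- sim$loops[sim$loops$chrom == cn, ]
      E <- expected_contact_band(cfg, n, max_d, loops, cluster_weights)
      X <- matrix(0, n, max_d + 1L)
      fin <- which(!is.na(E))
      X[fin] <- if (is.null(cfg$nb_dispersion)) stats::rpois(length(fin), E[fin])
                else stats::rnbinom(length(fin), mu = E[fin],
                                    size = cfg$nb_dispersion)
      idx <- which(X > 0, arr.ind = TRUE)
      contact_map(cn, cfg$resolution, n, idx[, 1],
                  idx[, 1] + idx[, 2] - 1L, X[idx])
    })
    stats::setNames(maps, sim$layout$chrom_names)
  })
}

# expected counts as a band matrix (NA beyond the chromosome end)
expected_contact_band <- function(cfg, n, max_d, loops, cluster_weights) {
  E <- matrix(NA_real_, n, max_d + 1L)
  for (d in 0:max_d) {
    k <- n - d
    if (k <= 0) break
    E[seq_len(k), d + 1L] <- sim_decay(cfg, d)
  }
  for (r in seq_len(nrow(loops))) {
    d <- loops$bin2[r] - loops$bin1[r]
    if (d <= max_d) {
      w <- cluster_weights[loops$cluster[r]]
      E[loops$bin1[r], d + 1L] <- E[loops$bin1[r], d + 1L] *
        (1 + (cfg$loop_enhancement - 1) * w)
    }
  }
  E
}

#' Ground-truth loop labels
#'
#' The planted loop bin pairs, per cluster, for use as evaluation labels.
#'
#' @param sim result of [simulate_genome()].
#' @param cluster optional cluster filter.
#' @return data.table with chrom, bin1, bin2, cluster.
#' @export
ground_truth_labels <- function(sim, cluster = NULL) {
  l <- data.table::as.data.table(sim$loops)
  if (!is.null(cluster)) {
    keep <- l$cluster %in% cluster
    l <- l[keep, ]
  }
  l[, c("chrom", "bin1", "bin2", "cluster"), with = FALSE]
}

#' Synthetic CTCF motif-score track
#'
#' Sparse positive track at accessibility resolution: strong scores at loop
#' anchor bins (CTCF is not cluster-specific) plus a sprinkle of decoy
#' sites.
#'
#' @param sim result of [simulate_genome()].
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @param acc_resolution track bin size (default 50).
#' @param decoy_rate fraction of bins given a random decoy score.
#' @return a `bin_track` with source `"motif"`.
#' @export
synthetic_ctcf_track <- function(sim, chrom, seed = 4L,
                                 acc_resolution = 50L, decoy_rate = 0.002) {
  cfg <- sim$config
  nb <- bin_count(sim$layout, chrom, acc_resolution)
  withr_seed(seed, {
    v <- numeric(nb)
    n_decoy <- stats::rbinom(1L, nb, decoy_rate)
    if (n_decoy > 0) {
      at <- sample.int(nb, n_decoy)
      v[at] <- stats::rexp(n_decoy, rate = 1 / 3)
    }
    loops <- sim$loops[sim$loops$chrom == chrom, ]
    fpb <- cfg$coacc_resolution %/% acc_resolution
    for (site in c(loops$site1, loops$site2)) {
      at <- (site - 1L) * fpb + fpb %/% 2L + 1L
      if (at >= 1 && at <= nb) v[at] <- max(v[at], stats::runif(1, 8, 15))
    }
    bin_track(chrom, acc_resolution, v, source = "motif")
  })
}

#' Simulate a complete paired scATAC + Hi-C dataset
#'
#' Runs the full generator and assembles ready-to-train
#' [contact_dataset()]s: one per chromosome for the bulk mixture and one per
#' cluster, sharing the scATAC draw (clusters use their own cells) and the
#' CTCF track. Contact maps are normalized with
#' [distance_stratified_zscore()], masked and clipped.
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed; per-stage seeds are derived from it.
#' @param metacell_k cells per metacell (capped at half the population).
#' @param clip target clip bounds.
#' @return list with `sim`, `scatac`, `bulk` (named dataset list by
#'   chromosome), `clusters` (list of named dataset lists), `truth_bulk`,
#'   `truth_clusters` (zscore_map lists), `counts_bulk`, `counts_clusters`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             metacell_k = 50L, clip = c(-16, 16)) {
  seed <- as.integer(seed) %% 100000L
  sim <- simulate_genome(config, seed = seed * 7L + 1L)
  sc <- simulate_scatac(sim, seed = seed * 7L + 2L)
  props <- as.numeric(table(factor(sim$cell_clusters,
                                   seq_len(config$n_clusters)))) /
    config$n_cells
  counts_bulk <- simulate_contacts(sim, props, seed = seed * 7L + 3L)
  counts_clusters <- lapply(seq_len(config$n_clusters), function(k) {
    w <- numeric(config$n_clusters); w[k] <- 1
    simulate_contacts(sim, w, seed = seed * 7L + 3L + k)
  })
  max_d <- as.integer(2e6 %/% config$resolution)
  build_set <- function(counts_by_chrom, cell_subset, mc_seed) {
    out <- list()
    for (cn in sim$layout$chrom_names) {
      counts <- counts_by_chrom[[cn]]
      mask <- low_signal_mask(counts)
      md <- min(2e6, (counts$n_bins - 1L) * config$resolution)
      z <- distance_stratified_zscore(counts, max_distance = md,
                                      mask = mask)
      z <- clip_targets(z, clip[1], clip[2])
      cb <- sc$cell_bins[[cn]][cell_subset, , drop = FALSE]
      frags <- sc$fragments[sc$fragments$chrom == cn &
                            sc$fragments$barcode %in%
                              sc$barcodes[cell_subset], ]
      acc <- insertion_matrix(frags, sc$barcodes[cell_subset], sim$layout,
                              cn, 50L)
      ctcf <- synthetic_ctcf_track(sim, cn, seed = seed * 7L + 6L)
      ds <- contact_dataset(cn, sim$layout, acc, cb, ctcf, z, mask = mask)
      ds <- add_metacells(ds, k = min(metacell_k, length(cell_subset) %/% 2L),
                          seed = mc_seed)
      out[[cn]] <- ds
    }
    out
  }
  bulk <- build_set(counts_bulk, seq_len(config$n_cells), seed * 7L + 10L)
  clusters <- lapply(seq_len(config$n_clusters), function(k) {
    build_set(counts_clusters[[k]], which(sim$cell_clusters == k),
              seed * 7L + 10L + k)
  })
  truth_of <- function(counts_by_chrom) {
    lapply(counts_by_chrom, function(m) {
      mask <- low_signal_mask(m)
      md <- min(2e6, (m$n_bins - 1L) * config$resolution)
      clip_targets(distance_stratified_zscore(m, md, mask), clip[1], clip[2])
    })
  }
  list(sim = sim, scatac = sc, bulk = bulk, clusters = clusters,
       truth_bulk = truth_of(counts_bulk),
       truth_clusters = lapply(counts_clusters, truth_of),
       counts_bulk = counts_bulk, counts_clusters = counts_clusters)
}
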