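#' Configuration for the synthetic-tissue generator
#'
#' The generator emulates the statistical structure the framework assumes:
#' an H&E-like image whose tumor region is spatially contiguous and darker
#' than surrounding tissue by a fixed gray-level contrast; spots on a
#' regular grid labeled tumor when their center falls inside the region;
#' log-normal base expression with gene-specific baselines; a set of marker
#' genes shifted on the log scale in tumor spots; one pass of neighbor
#' mixing over the same adjacency the models will use (spatial
#' autocorrelation); and a bulk vector equal to the spot-average plus
#' Gaussian noise.
#'
#' @param grid `c(rows, cols)` of the spot lattice (default `c(12, 12)`).
#' @param n_genes Number of genes `p` (default 50).
#' @param n_marker_genes Number of tumor marker genes (default 5; the first
#'   `n_marker_genes` gene columns).
#' @param effect_size Log-scale shift of marker genes in tumor spots
#'   (default 2).
#' @param spot_spacing Pixel distance between adjacent grid spots
#'   (default 32).
#' @param margin Pixel margin around the outermost spots (default 128, so
#'   224-pixel crops always fit).
#' @param image_side Image side in pixels; `NULL` (default) derives the
#'   smallest side fitting the grid and margins.
#' @param tumor_center Tumor-disk center as fractions of the image side
#'   (default `c(0.5, 0.5)`).
#' @param tumor_radius_frac Tumor-disk radius as a fraction of the image
#'   side (default 0.22).
#' @param intensity_contrast Mean gray-level offset of tumor vs non-tumor
#'   texture (default 40).
#' @param tissue_gray Mean gray level of non-tumor tissue (default 200).
#' @param pixel_noise_sd Per-pixel Gaussian texture noise (default 10).
#' @param gene_mean_log_sd SD of gene-specific baseline log-means
#'   (default 1).
#' @param base_log_sd Per-spot log-normal spread around the gene baseline
#'   (default 0.5).
#' @param spatial_autocorrelation Neighbor-mixing weight in `[0, 1)`
#'   (default 0.3).
#' @param adjacency_threshold Threshold used both for the mixing graph and
#'   intended for the downstream spot graph (default 0.15).
#' @param noise_sd Additive post-mixing expression noise (default 0.1).
#' @param bulk_noise_sd SD of the Gaussian noise added to the spot-average
#'   to form the bulk vector (default 0.05).
#' @param gene_log_means Optional length-`p` vector of baseline log-means
#'   (drawn when `NULL`; a cohort shares one draw).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid = c(12L, 12L), n_genes = 50L,
                       n_marker_genes = 5L, effect_size = 2,
                       spot_spacing = 32L, margin = 128L, image_side = NULL,
                       tumor_center = c(0.5, 0.5), tumor_radius_frac = 0.22,
                       intensity_contrast = 40, tissue_gray = 200,
                       pixel_noise_sd = 10,
                       gene_mean_log_sd = 1, base_log_sd = 0.5,
                       spatial_autocorrelation = 0.3,
                       adjacency_threshold = 0.15,
                       noise_sd = 0.1, bulk_noise_sd = 0.05,
                       gene_log_means = NULL, seed = 1L) {
  stopifnot(n_genes >= n_marker_genes,
            spatial_autocorrelation >= 0, spatial_autocorrelation < 1)
  span <- (max(grid) - 1L) * spot_spacing
  min_side <- span + 2L * margin
  if (is.null(image_side)) image_side <- min_side
  if (image_side < min_side) {
    stop("image_side ", image_side, " too small: grid plus ", margin,
         "-pixel margins needs at least ", min_side)
  }
  structure(list(grid = as.integer(grid), n_genes = as.integer(n_genes),
                 n_marker_genes = as.integer(n_marker_genes),
                 effect_size = effect_size,
                 spot_spacing = as.integer(spot_spacing),
                 margin = as.integer(margin),
                 image_side = as.integer(image_side),
                 tumor_center = tumor_center,
                 tumor_radius_frac = tumor_radius_frac,
                 intensity_contrast = intensity_contrast,
                 tissue_gray = tissue_gray, pixel_noise_sd = pixel_noise_sd,
                 gene_mean_log_sd = gene_mean_log_sd,
                 base_log_sd = base_log_sd,
                 spatial_autocorrelation = spatial_autocorrelation,
                 adjacency_threshold = adjacency_threshold,
                 noise_sd = noise_sd, bulk_noise_sd = bulk_noise_sd,
                 gene_log_means = gene_log_means, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one paired sample
#'
#' Produces an image, spot table with tumor labels, spot expression matrix,
#' and bulk vector under one seed (byte-identical outputs for identical
#' config and seed). An error is raised when the tumor region captures zero
#' or all spots.
#'
#' @param cfg A [sim_config()].
#' @return List with `image` (`side x side x 3`, 0--255), `spots` (spot
#'   table with `label`), `labels` (0/1 vector), `expr` (`g x p`, rows =
#'   spots, columns named `gene_1..gene_p`), `bulk` (named length-`p`
#'   vector) and `gene_log_means`.
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  side <- cfg$image_side
  nr <- cfg$grid[1L]; nc <- cfg$grid[2L]
  g <- nr * nc; p <- cfg$n_genes

  # spot lattice centered in the image
  xs0 <- cfg$margin + (side - 2L * cfg$margin -
                       (nc - 1L) * cfg$spot_spacing) %/% 2L
  ys0 <- cfg$margin + (side - 2L * cfg$margin -
                       (nr - 1L) * cfg$spot_spacing) %/% 2L
  spots <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  spots <- data.frame(
    spot_id = sprintf("spot_%03d", seq_len(g)),
    x = xs0 + spots$col * cfg$spot_spacing,
    y = ys0 + spots$row * cfg$spot_spacing,
    stringsAsFactors = FALSE)

  cx <- cfg$tumor_center[1L] * side
  cy <- cfg$tumor_center[2L] * side
  radius <- cfg$tumor_radius_frac * side
  labels <- as.integer((spots$x - cx)^2 + (spots$y - cy)^2 <= radius^2)
  if (sum(labels) == 0L || sum(labels) == g) {
    stop("tumor region captures ", sum(labels), " of ", g,
         " spots; adjust tumor_center/tumor_radius_frac")
  }
  spots$label <- ifelse(labels == 1L, "tumor", "non_tumor")

  # image: class-dependent mean gray + Gaussian pixel noise
  colv <- matrix(seq_len(side) - 0.5, side, side, byrow = TRUE)  # x coord
  rowv <- matrix(seq_len(side) - 0.5, side, side)                # y coord
  in_tumor <- (colv - cx)^2 + (rowv - cy)^2 <= radius^2
  base <- matrix(cfg$tissue_gray, side, side)
  base[in_tumor] <- cfg$tissue_gray - cfg$intensity_contrast
  image <- array(0, c(side, side, 3L))
  for (ch in 1:3) {
    image[, , ch] <- pmin(pmax(
      base + stats::rnorm(side * side, sd = cfg$pixel_noise_sd), 0), 255)
  }

  # expression: gene baselines, marker shift, neighbor mixing, noise
  mu <- cfg$gene_log_means
  if (is.null(mu)) mu <- stats::rnorm(p, sd = cfg$gene_mean_log_sd)
  L <- matrix(mu, g, p, byrow = TRUE) +
    matrix(stats::rnorm(g * p, sd = cfg$base_log_sd), g, p)
  if (cfg$n_marker_genes > 0L) {
    mk <- seq_len(cfg$n_marker_genes)
    L[labels == 1L, mk] <- L[labels == 1L, mk] + cfg$effect_size
  }
  E0 <- exp(L)
  w <- cfg$spatial_autocorrelation
  if (w > 0) {
    adj <- suppressMessages(
      build_adjacency(spots, threshold = cfg$adjacency_threshold))
    deg <- rowSums(adj)
    M <- adj / pmax(deg, 1)
    E <- (1 - w) * E0 + w * (M %*% E0)
    E[deg == 0, ] <- E0[deg == 0, ]               # isolated spots unmixed
  } else {
    E <- E0
  }
  if (cfg$noise_sd > 0) {
    E <- E + matrix(stats::rnorm(g * p, sd = cfg$noise_sd), g, p)
  }
  E <- pmax(E, 0)
  dimnames(E) <- list(spots$spot_id, paste0("gene_", seq_len(p)))

  bulk <- colMeans(E)
  if (cfg$bulk_noise_sd > 0) {
    bulk <- bulk + stats::rnorm(p, sd = cfg$bulk_noise_sd)
  }
  names(bulk) <- colnames(E)

  list(image = image, spots = spots, labels = labels, expr = E, bulk = bulk,
       gene_log_means = mu)
}

#' Simulate a cohort of samples
#'
#' Samples share one draw of gene baseline log-means; the tumor-disk center
#' and radius vary per sample (so tumor fractions differ across the
#' cohort), and each sample gets its own derived seed. With `dir` set, every
#' sample is written in the formats the other modules read (PNG image, spot
#' and expression TSVs, bulk TSV) plus a `manifest.tsv` enumerating the
#' files; otherwise the samples are returned in memory.
#'
#' @param n_samples Number of samples.
#' @param cfg A [sim_config()]; `cfg$seed` seeds the whole cohort.
#' @param dir Optional output directory.
#' @param vary_tumor Vary tumor-disk center/radius across samples
#'   (default `TRUE`).
#' @return List of samples (invisibly, with `$manifest` attached, when
#'   `dir` is set).
#' @export
simulate_cohort <- function(n_samples, cfg, dir = NULL, vary_tumor = TRUE) {
  stopifnot(n_samples >= 1L)
  set.seed(cfg$seed)
  mu <- cfg$gene_log_means
  if (is.null(mu)) mu <- stats::rnorm(cfg$n_genes, sd = cfg$gene_mean_log_sd)
  centers <- matrix(0.5, n_samples, 2L)
  radii <- rep(cfg$tumor_radius_frac, n_samples)
  if (vary_tumor) {
    centers <- matrix(stats::runif(2L * n_samples, 0.4, 0.6), n_samples, 2L)
    radii <- stats::runif(n_samples, 0.15, 0.3)
  }
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg_i <- cfg
    cfg_i$gene_log_means <- mu
    cfg_i$tumor_center <- centers[i, ]
    cfg_i$tumor_radius_frac <- radii[i]
    cfg_i$seed <- cfg$seed + 1000L * i
    samples[[i]] <- simulate_sample(cfg_i)
    samples[[i]]$sample_id <- sprintf("sample_%02d", i)
  }
  if (is.null(dir)) return(samples)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    id <- s$sample_id
    paths <- list(image = file.path(dir, paste0(id, "_image.png")),
                  spots = file.path(dir, paste0(id, "_spots.tsv")),
                  expr = file.path(dir, paste0(id, "_expr.tsv")),
                  bulk = file.path(dir, paste0(id, "_bulk.tsv")))
    write_image(s$image, paths$image)
    write_spot_table(s$spots, paths$spots)
    write_expression(s$expr, paths$expr)
    write_bulk(s$bulk, paths$bulk)
    data.frame(sample_id = id, image = paths$image, spots = paths$spots,
               expr = paths$expr, bulk = paths$bulk, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- samples
  attr(out, "manifest") <- manifest
  invisible(out)
}
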