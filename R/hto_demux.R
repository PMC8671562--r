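#' Method-of-moments negative-binomial fit to background counts
#'
#' Fits NB(mu, size) with variance `mu + mu^2/size` by matching the sample
#' mean and variance: `mu = mean(x)`, `size = mu^2 / (var(x) - mu)`.  When
#' the sample variance does not exceed the mean the fit falls back to a
#' Poisson (`size = Inf`).
#'
#' @param x Non-negative integer counts for one hashtag over the selected
#'   background cells; at least 20 values are required.
#' @return A list `mu`, `size` (class `nb_params`).
#' @export
fit_background_nb <- function(x) {
  if (length(x) < 20L)
    stop("fit_background_nb: fewer than 20 background cells; ",
         "supply a manual threshold instead", call. = FALSE)
  if (any(x < 0)) stop("fit_background_nb: negative counts", call. = FALSE)
  mu <- mean(x)
  s2 <- stats::var(x)
  size <- if (s2 > mu) mu^2 / (s2 - mu) else Inf
  structure(list(mu = mu, size = size), class = "nb_params")
}

#' Integer quantile of a negative-binomial (or Poisson) distribution
#'
#' The smallest integer `k` with `CDF(k) >= q`, with the CDF accumulated by
#' direct term-by-term summation of the mass function (`size = Inf` selects
#' the Poisson limit).  `mu = 0` returns 0 for any `q`.
#'
#' @param params An `nb_params` list (`mu`, `size`), e.g. from
#'   [fit_background_nb()].
#' @param q Probability in (0, 1).
#' @return Integer threshold.
#' @export
nb_quantile <- function(params, q = 0.99) {
  mu <- params$mu; size <- params$size
  if (q <= 0 || q >= 1) stop("nb_quantile: q must be in (0, 1)",
                             call. = FALSE)
  if (mu < 0) stop("nb_quantile: mu must be >= 0", call. = FALSE)
  if (mu == 0) return(0L)
  pmf <- if (is.infinite(size)) function(k) stats::dpois(k, lambda = mu)
         else function(k) stats::dnbinom(k, size = size, mu = mu)
  sd_hi <- sqrt(mu + if (is.infinite(size)) 0 else mu^2 / size)
  cap <- ceiling(mu + 20 * sd_hi) + 1000L
  k <- 0L
  cdf <- pmf(0L)
  while (cdf < q && k < cap) {
    k <- k + 1L
    cdf <- cdf + pmf(k)
  }
  as.integer(k)
}

# Centered log-ratio transform across hashtags, cells x tags.
# Used only for background-cell selection, never for thresholding.
.clr_hto <- function(counts) {
  lg <- log1p(t(as.matrix(counts)))
  lg - rowMeans(lg)
}

#' Demultiplex hashtag-oligo counts
#'
#' Classifies each cell as singlet, doublet or negative from a hashtags x
#' cells count matrix.  For each hashtag a background negative-binomial is
#' fitted (method of moments) and the positivity threshold is set at the
#' `q`-quantile of that distribution (default 0.99).  A cell is positive
#' for a tag when its count is strictly greater than the tag's threshold
#' (ties at the threshold are negative); cells positive for exactly one tag
#' are singlets, for two or more are doublets, for none are negatives.
#'
#' Background cells per tag are selected by k-means clustering (k = number
#' of tags + 1) of the CLR-transformed counts: background for tag t is the
#' cluster with the lowest mean CLR value for t, i.e. cells confidently
#' negative for that tag.  (Taking the complement of the highest cluster
#' instead would sweep doublet cells carrying t as their second tag into
#' the background and inflate the fitted variance, and with it the
#' threshold.)  When clustering degenerates or leaves fewer than 20
#' background cells, the fallback takes the cells at or below the tag's
#' 90th count percentile.
#'
#' @param hto Hashtags x cells count matrix with dimnames.
#' @param q Quantile for the positivity threshold.
#' @param seed Seed for the k-means initialisation (classification is
#'   deterministic given `hto`, `q` and `seed`).
#' @return Data frame `barcode`, `class` (`singlet`/`doublet`/`negative`),
#'   `assigned_tag` (the tag for singlets, `NA` otherwise), with the
#'   per-tag integer thresholds attached as attribute `thresholds`.
#' @export
demux_hashtags <- function(hto, q = 0.99, seed = 1L) {
  hto <- as.matrix(hto)
  if (nrow(hto) < 1L) stop("demux_hashtags: need at least one hashtag",
                           call. = FALSE)
  n_tags <- nrow(hto)
  n_cells <- ncol(hto)
  tags <- rownames(hto)
  if (is.null(tags)) tags <- paste0("HTO", seq_len(n_tags))

  cluster_of <- NULL
  clr <- NULL
  if (n_tags >= 2L && n_cells > n_tags + 1L) {
    clr <- .clr_hto(hto)
    km <- tryCatch({
      old <- .save_rng()
      on.exit(.restore_rng(old), add = TRUE)
      set.seed(seed)
      stats::kmeans(clr, centers = n_tags + 1L, nstart = 10L,
                    iter.max = 100L)
    }, error = function(e) NULL)
    if (!is.null(km)) cluster_of <- km$cluster
  }

  thresholds <- integer(n_tags)
  for (t in seq_len(n_tags)) {
    counts_t <- hto[t, ]
    bg <- NULL
    if (!is.null(cluster_of)) {
      means <- sort(tapply(clr[, t], cluster_of, mean))
      # accumulate clusters from the most negative upward until enough
      # background cells, never touching the highest (positive) cluster
      use <- character(0)
      for (cl in names(means)[-length(means)]) {
        use <- c(use, cl)
        if (sum(cluster_of %in% as.integer(use)) >= 20L) break
      }
      cand <- counts_t[cluster_of %in% as.integer(use)]
      if (length(cand) >= 20L) bg <- cand
    }
    if (is.null(bg))
      bg <- counts_t[counts_t <= stats::quantile(counts_t, 0.90)]
    fit <- fit_background_nb(bg)
    thresholds[t] <- nb_quantile(fit, q)
  }
  names(thresholds) <- tags

  positive <- hto > thresholds  # column-wise recycling over cells
  n_pos <- Matrix::colSums(positive)
  cls <- ifelse(n_pos == 0L, "negative",
                ifelse(n_pos == 1L, "singlet", "doublet"))
  assigned <- rep(NA_character_, n_cells)
  single <- which(n_pos == 1L)
  if (length(single))
    assigned[single] <- tags[apply(positive[, single, drop = FALSE], 2L,
                                   which.max)]
  out <- data.frame(barcode = colnames(hto), class = cls,
                    assigned_tag = assigned, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

# Save / restore the global RNG state so seeded internals do not perturb
# the caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
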