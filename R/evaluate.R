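# The positive-predictive-value evaluation protocol.
#
# All within-positive-set and within-negative-set pair scores are
# pooled and sorted in descending order; the PPV is the fraction of
# positive pairs in the top half.  1 means perfect separation of the
# two sets, 0.5 means no statistical power.  Ties straddling the
# cutoff are resolved fractionally (a tied positive counts with its
# expected inclusion probability over uniform tie orderings), which
# keeps the protocol deterministic and makes ppv(pos, neg) +
# ppv(neg, pos) = 1 hold exactly.

#' Positive predictive value of a score separation
#'
#' @param pos_scores,neg_scores Equal-length numeric vectors of
#'   within-positive-set and within-negative-set pair scores.
#' @return PPV in `[0, 1]`.
#' @export
#' @examples
#' ppv(c(3, 2), c(1, 0))  # 1: perfect separation
ppv <- function(pos_scores, neg_scores) {
  m <- length(pos_scores)
  if (m < 1L || length(neg_scores) != m)
    stop("`pos_scores` and `neg_scores` must be non-empty and of equal length",
         call. = FALSE)
  pool <- c(pos_scores, neg_scores)
  if (anyNA(pool)) stop("scores must not contain NA", call. = FALSE)
  thr <- sort(pool, decreasing = TRUE)[m]
  n_above <- sum(pool > thr)
  pos_above <- sum(pos_scores > thr)
  tied <- sum(pool == thr)
  tied_pos <- sum(pos_scores == thr)
  slots <- m - n_above
  (pos_above + slots * tied_pos / tied) / m
}

# background specification -> background argument for build_experiment_sets
.resolve_background <- function(bg) {
  if (inherits(bg, "background_model") || is.character(bg) && length(bg) > 1L)
    return(bg)
  if (is.character(bg) && length(bg) == 1L) return(read_fasta(bg))
  if (is.list(bg)) {
    if (!is.null(bg$path)) return(read_fasta(bg$path))
    probs <- unlist(bg$probs) %||% c(0.3, 0.2, 0.2, 0.3)
    order <- bg$order %||% 0L
    if (order == 0L) return(background_model(probs, order = 0L))
    pi <- matrix(unlist(bg$transitions), 4L, 4L, byrow = TRUE)
    return(background_model(probs, pi = pi, order = 1L))
  }
  stop("cannot interpret the background specification", call. = FALSE)
}

.default_background <- function() {
  # AT-rich order-0 composition, emulating intergenic DNA
  background_model(c(0.3, 0.2, 0.2, 0.3), order = 0L)
}

#' Run a PPV parameter-sweep experiment
#'
#' For each replicate, builds a negative/positive set pair with
#' [build_experiment_sets()]; for each measure and resolution in the
#' grid, scores all within-set pairs with [pairwise_matrix()] and
#' computes the PPV with [ppv()]. Reported per grid cell: mean PPV
#' over replicates and its standard error.
#'
#' @param config A named list (or the parsed YAML of [cli_evaluate()])
#'   with fields: `n`, `length`, `replicates`, `seed`, `measures`
#'   (character vector), `k` (integer vector of resolutions),
#'   `implant` (list with `motifs`, `insertion_prob`, optional `mode`),
#'   and optional `background` (model spec or FASTA path; default an
#'   AT-rich order-0 model), `sigma` (default 0.7), `order` (default
#'   1), `revcomp` (default TRUE), `include_nonoverlap` (default
#'   FALSE), `pseudocount` (default 1), `variance` (default "exact"),
#'   `paired` (default TRUE).
#' @return A data frame with one row per measure x resolution:
#'   parameters, `mean_ppv`, `se_ppv`, `replicates`.
#' @export
run_experiment <- function(config) {
  required <- c("n", "length", "replicates", "seed", "measures", "k",
                "implant")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("experiment config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- config$n
  len <- config$length
  reps <- config$replicates
  if (!.is_count(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (!.is_count(len) || len < 1L)
    stop("`length` must be a positive integer", call. = FALSE)
  if (!.is_count(reps) || reps < 1L)
    stop("`replicates` must be a positive integer", call. = FALSE)
  measures <- match.arg(unlist(config$measures),
                        c("d2", "d2s", "d2star", "ep2", "ep2star"),
                        several.ok = TRUE)
  ks <- as.integer(unlist(config$k))
  if (any(is.na(ks)) || any(ks < 1L) || any(ks > len))
    stop("`k` values must be integers in [1, length]", call. = FALSE)
  spec <- implant_spec(unlist(config$implant$motifs),
                       config$implant$insertion_prob,
                       mode = config$implant$mode %||% "revised")
  background <- if (is.null(config$background)) .default_background()
                else .resolve_background(config$background)
  sigma <- config$sigma %||% 0.7
  order <- config$order %||% 1L
  revcomp <- config$revcomp %||% TRUE
  incl <- config$include_nonoverlap %||% FALSE
  pc <- config$pseudocount %||% 1
  variance <- config$variance %||% "exact"
  paired <- config$paired %||% TRUE
  seed <- as.integer(config$seed)

  grid <- expand.grid(measure = measures, k = ks, stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow(grid), reps)
  for (r in seq_len(reps)) {
    sets <- build_experiment_sets(background, n, len, spec,
                                  seed = .derive_seed(seed, 104729L * r),
                                  paired = paired)
    for (g in seq_len(nrow(grid))) {
      args <- list(measure = grid$measure[g], k = grid$k[g], sigma = sigma,
                   order = order, include_nonoverlap = incl,
                   pseudocount = pc, variance = variance)
      if (grid$measure[g] %in% c("ep2", "ep2star")) args$revcomp <- revcomp
      pos <- .upper_scores(do.call(pairwise_matrix,
                                   c(list(sets$positive), args)))
      neg <- .upper_scores(do.call(pairwise_matrix,
                                   c(list(sets$negative), args)))
      vals[g, r] <- ppv(pos, neg)
    }
  }
  data.frame(measure = grid$measure, k = grid$k, sigma = sigma,
             order = order, revcomp = revcomp,
             insertion_prob = spec$insertion_prob,
             n = n, length = len, replicates = reps,
             mean_ppv = rowMeans(vals),
             se_ppv = apply(vals, 1L, stats::sd) / sqrt(reps))
}
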