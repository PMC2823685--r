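# Score every width-W window of a coded sequence against a weight matrix.
# Returns a numeric vector of length L - W + 1 (windows overlapping N score
# -Inf). Vectorised over window start by accumulating one matrix column at
# a time.
window_scores <- function(codes, weights) {
  W <- ncol(weights)
  n <- length(codes) - W + 1L
  if (n < 1) return(numeric(0))
  z <- numeric(n)
  na_hit <- rep(FALSE, n)
  for (k in seq_len(W)) {
    ck <- codes[k:(k + n - 1L)]
    na_hit <- na_hit | is.na(ck)
    contrib <- weights[cbind(ck, k)]
    contrib[is.na(contrib)] <- 0
    z <- z + contrib
  }
  z[na_hit] <- -Inf
  z
}

# Both-strand window scores for one sequence under a model. Reverse-strand
# score at forward position p is the score of the reverse complement of the
# window. For palindromic models the two strands agree; scores are averaged
# with the reverse reading so equality is exact.
scores_both_strands <- function(model, seq) {
  codes <- seq_codes(seq)
  fwd <- window_scores(codes, model$weights)
  n <- length(fwd)
  if (n == 0) return(list(fwd = numeric(0), rev = numeric(0)))
  rc_codes <- rev(5L - codes)  # A<->T, C<->G on the reversed sequence
  rev_raw <- window_scores(rc_codes, model$weights)
  rev_mapped <- rev(rev_raw)   # pos p (0-based) maps to rc-pos L - W - p
  if (model$palindromic) {
    avg <- (fwd + rev_mapped) / 2
    list(fwd = avg, rev = avg)
  } else {
    list(fwd = fwd, rev = rev_mapped)
  }
}

#' Discover a shared palindromic motif in upstream regions
#'
#' One-occurrence-per-sequence site sampler: each region is assigned one
#' candidate window; iteratively, a model is rebuilt from all other regions'
#' windows (with palindromic symmetrisation) and the held-out region's best
#' window over both strands is re-chosen. A full update pass is kept only if
#' the total information content of the model built from all chosen windows
#' increases, so the objective is non-decreasing across iterations; the best
#' of several random restarts is returned. Ties between equal-scoring
#' windows go to the leftmost position, forward strand first.
#'
#' After convergence a training-min threshold is set on the returned model;
#' regions whose window falls below an explicitly supplied `threshold` are
#' reported siteless, provided at least `min_regions_with_site` of the
#' regions keep a site (with the default training-min threshold no window
#' can fall below it, so nothing is dropped).
#'
#' @param regions Character vector of region sequences, or a data frame with
#'   columns `gene_id`/`region_id` and `seq` (e.g. from
#'   [extract_upstream()]).
#' @param width Motif width (odd when `palindromic`; the Zur operator is a
#'   10-1-10 inverted repeat, width 21).
#' @param palindromic Constrain the model to dyad symmetry.
#' @param restarts,max_iter Random restarts and maximum passes per restart.
#' @param seed Integer seed; the search is deterministic given seed+inputs.
#' @param min_regions_with_site Minimum fraction of regions that must retain
#'   a site when dropping below-threshold windows.
#' @param pseudocount Passed to [build_motif()].
#' @param threshold Optional explicit Z threshold for the post-convergence
#'   drop rule; default uses the model's own training minimum.
#' @return Object of class `motif_discovery`: list with `model` (a
#'   `pwm_model` with threshold set), `sites` (tibble `region_id`,
#'   `position` 0-based within the region, `strand`, `sequence`, `z`),
#'   `objective` (IC trajectory of the winning restart), `restart`.
#' @export
discover_motif <- function(regions, width = 21, palindromic = TRUE,
                           restarts = 10, max_iter = 50, seed = 1,
                           min_regions_with_site = 0.5, pseudocount = 0.5,
                           threshold = NULL) {
  if (is.data.frame(regions)) {
    ids <- regions$region_id %||% regions$gene_id %||% as.character(seq_len(nrow(regions)))
    seqs <- regions$seq
  } else {
    seqs <- unname(regions)
    ids <- names(regions) %||% as.character(seq_along(seqs))
  }
  stopifnot(width >= 2)
  if (palindromic && width %% 2 == 0) {
    stop("palindromic motifs need an odd width (dyad with unpaired centre)", call. = FALSE)
  }
  usable <- nchar(seqs) >= width
  if (!any(usable)) stop("all regions are shorter than the motif width", call. = FALSE)
  seqs <- toupper(seqs[usable]); ids <- ids[usable]
  n <- length(seqs)
  if (n < 3) stop("need at least 3 regions", call. = FALSE)

  take_window <- function(i, pos, strand) {
    s <- substr(seqs[i], pos + 1L, pos + width)
    if (strand == "-") revcomp(s) else s
  }
  model_from <- function(windows) {
    build_motif(windows, palindromic = palindromic, pseudocount = pseudocount)
  }
  total_ic <- function(windows) sum(information_content(model_from(windows)))

  run_restart <- function() {
    pos <- vapply(seqs, function(s) sample.int(nchar(s) - width + 1L, 1L) - 1L, 0L,
                  USE.NAMES = FALSE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    windows <- mapply(take_window, seq_len(n), pos, strand)
    obj <- total_ic(windows)
    trajectory <- obj
    for (iter in seq_len(max_iter)) {
      prev <- list(pos = pos, strand = strand, windows = windows)
      for (i in seq_len(n)) {
        m <- model_from(windows[-i])
        sc <- scores_both_strands(m, seqs[i])
        best_f <- which.max(sc$fwd); best_r <- which.max(sc$rev)
        if (sc$fwd[best_f] >= sc$rev[best_r]) {
          pos[i] <- best_f - 1L; strand[i] <- "+"
        } else {
          pos[i] <- best_r - 1L; strand[i] <- "-"
        }
        windows[i] <- take_window(i, pos[i], strand[i])
      }
      new_obj <- total_ic(windows)
      if (new_obj <= obj + 1e-10) {
        # keep the previous state unless this pass strictly improved
        if (new_obj < obj) {
          pos <- prev$pos; strand <- prev$strand; windows <- prev$windows
        } else {
          trajectory <- c(trajectory, new_obj)
          obj <- new_obj
        }
        break
      }
      obj <- new_obj
      trajectory <- c(trajectory, obj)
    }
    list(pos = pos, strand = strand, windows = windows, obj = obj,
         trajectory = trajectory)
  }

  best <- withr::with_seed(seed, {
    runs <- lapply(seq_len(restarts), function(r) c(run_restart(), restart = r))
    runs[[which.max(vapply(runs, `[[`, 0.0, "obj"))]]
  })

  model <- set_threshold_from_training(model_from(best$windows))
  sites <- tibble::tibble(region_id = ids, position = best$pos,
                          strand = best$strand, sequence = best$windows,
                          z = score_sites(model, best$windows)$z)
  drop_at <- threshold %||% model$threshold
  keep <- sites$z >= drop_at
  min_keep <- ceiling(min_regions_with_site * n)
  if (sum(keep) < min_keep) {
    ord <- order(sites$z, decreasing = TRUE)
    keep[ord[seq_len(min_keep)]] <- TRUE
  }
  structure(list(model = model, sites = sites[keep, ],
                 siteless = ids[!keep], objective = best$trajectory,
                 restart = best$restart),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf("<motif_discovery> %d sites, consensus %s, total IC %.2f bits (restart %d, %d passes)\n",
              nrow(x$sites), as.character(consensus(x$model)),
              sum(information_content(x$model)), x$restart, length(x$objective)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.motif_discovery <- function(x, ...) x$sites

#' @exportS3Method generics::glance
glance.motif_discovery <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$sites), n_siteless = length(x$siteless),
                 total_ic = sum(information_content(x$model)),
                 threshold = x$model$threshold,
                 passes = length(x$objective), restart = x$restart)
}
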