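#' Build a positional-weight-matrix motif model
#'
#' Counts are accumulated per column from the training sites; for
#' palindromic models each site also contributes its reverse complement, so
#' the count matrix (and hence every derived weight) satisfies
#' `N(b, k) = N(comp(b), W - 1 - k)`. Weights are centred log counts,
#'
#' \deqn{w(b,k) = \ln(N(b,k) + c) - \frac{1}{4}\sum_{b'} \ln(N(b',k) + c),}
#'
#' with pseudocount `c` (default 0.5), which makes every column sum to zero.
#' The Z-score of a candidate site is the sum of its positional weights; the
#' scan threshold is conventionally the lowest Z-score observed in the
#' training set ([set_threshold_from_training()]), never a hard-coded value.
#'
#' @param sites Character vector (>= 2) of equal-length sites over
#'   `{A,C,G,T}`.
#' @param palindromic Symmetrise counts with reverse complements? For
#'   palindromic models forward and reverse scan scores are exactly equal.
#' @param pseudocount Added to every count before taking logs.
#' @return Object of class `pwm_model`: list with `width`, `counts` and
#'   `weights` (4 x W matrices, rows A,C,G,T), `palindromic`, `pseudocount`,
#'   `threshold` (NA until set), `training_sites`.
#' @seealso [score_sites()], [set_threshold_from_training()], [consensus()],
#'   [information_content()], [scan_sequence()]
#' @export
#' @examples
#' m <- build_motif(cgl_zur_targets()$motif[!is.na(cgl_zur_targets()$motif)])
#' round(colSums(m$weights), 12)
build_motif <- function(sites, palindromic = TRUE, pseudocount = 0.5) {
  stopifnot(length(sites) >= 2, pseudocount >= 0)
  sites <- check_dna(sites, allow_n = FALSE, what = "training site")
  W <- unique(nchar(sites))
  if (length(W) != 1) stop("training sites have inconsistent lengths", call. = FALSE)
  counted <- if (palindromic) c(sites, revcomp(sites)) else sites
  counts <- matrix(0, 4, W, dimnames = list(DNA_BASES, NULL))
  for (s in counted) {
    codes <- seq_codes(s)
    counts[cbind(codes, seq_len(W))] <- counts[cbind(codes, seq_len(W))] + 1
  }
  model <- structure(list(width = W, counts = counts,
                          weights = counts_to_weights(counts, pseudocount),
                          palindromic = palindromic, pseudocount = pseudocount,
                          threshold = NA_real_, training_sites = sites),
                     class = "pwm_model")
  model
}

counts_to_weights <- function(counts, pseudocount) {
  w <- log(counts + pseudocount)
  sweep(w, 2, colMeans(w))
}

#' Score candidate sites against a motif model
#'
#' The Z-score is the sum of positional nucleotide weights over the site.
#' Sites containing ambiguity codes score `-Inf`. For palindromic models the
#' forward and reverse-complement readings are averaged, which makes
#' `score(s) == score(revcomp(s))` exact (the two readings contain the same
#' weight terms, so the average is identical either way).
#'
#' @param model A `pwm_model`.
#' @param seqs Character vector of sequences of the model width.
#' @return Tibble with columns `sequence`, `z`.
#' @export
score_sites <- function(model, seqs) {
  stopifnot(inherits(model, "pwm_model"))
  if (any(nchar(seqs) != model$width)) {
    stop("sequences must have the model width (", model$width, ")", call. = FALSE)
  }
  tibble::tibble(sequence = toupper(seqs),
                 z = vapply(toupper(seqs), score_one, 0.0, model = model,
                            USE.NAMES = FALSE))
}

score_one <- function(seq, model) {
  raw <- function(s) {
    codes <- seq_codes(s)
    if (anyNA(codes)) return(-Inf)
    sum(model$weights[cbind(codes, seq_len(model$width))])
  }
  if (model$palindromic) (raw(seq) + raw(revcomp(seq))) / 2 else raw(seq)
}

#' Set the scan threshold from the training set
#'
#' The threshold is the minimum Z-score of the model over its own training
#' sites, so no training site is ever rejected by its own model.
#'
#' @param model A `pwm_model` with at least one training site.
#' @return The model with `threshold` set.
#' @export
set_threshold_from_training <- function(model) {
  stopifnot(inherits(model, "pwm_model"), length(model$training_sites) >= 1)
  model$threshold <- min(score_sites(model, model$training_sites)$z)
  model
}

#' Consensus sequence, information content, and logo frequencies
#'
#' `consensus()` returns the per-column argmax base (ties broken
#' alphabetically and flagged in the `tie_positions` attribute).
#' `information_content()` returns per-column bits,
#' `IC_k = 2 + sum_b f(b,k) log2 f(b,k)`, with `f` the pseudocounted column
#' frequencies. `logo_table()` returns the frequencies themselves in long
#' form (per position they sum to 1).
#'
#' @param model A `pwm_model`.
#' @param pseudocount Pseudocount for the frequencies; defaults to the
#'   model's own.
#' @return `consensus()`: a string with attribute `tie_positions`;
#'   `information_content()`: numeric vector of length `width`;
#'   `logo_table()`: tibble `position`, `base`, `freq`.
#' @export
consensus <- function(model) {
  stopifnot(inherits(model, "pwm_model"))
  idx <- apply(model$counts, 2, which.max)  # which.max ties -> lowest index = alphabetical
  ties <- which(apply(model$counts, 2, function(col) sum(col == max(col)) > 1))
  out <- paste(DNA_BASES[idx], collapse = "")
  attr(out, "tie_positions") <- as.integer(ties)
  out
}

column_freqs <- function(model, pseudocount = model$pseudocount) {
  f <- model$counts + pseudocount
  sweep(f, 2, colSums(f), "/")
}

#' @rdname consensus
#' @export
information_content <- function(model, pseudocount = model$pseudocount) {
  f <- column_freqs(model, pseudocount)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  2 + colSums(plogp)
}

#' @rdname consensus
#' @export
logo_table <- function(model, pseudocount = model$pseudocount) {
  f <- column_freqs(model, pseudocount)
  tibble::tibble(position = rep(seq_len(model$width), each = 4),
                 base = rep(DNA_BASES, model$width),
                 freq = as.vector(f))
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> width %d, %s, %d training sites, pseudocount %g\n",
              x$width, if (x$palindromic) "palindromic" else "asymmetric",
              length(x$training_sites), x$pseudocount))
  cat(sprintf("  consensus: %s\n", as.character(consensus(x))))
  cat(sprintf("  total IC: %.2f bits; threshold: %s\n",
              sum(information_content(x)),
              if (is.na(x$threshold)) "unset" else sprintf("%.3f", x$threshold)))
  invisible(x)
}

#' Tidiers for motif models
#'
#' `tidy()` returns one row per (position, base) with counts, weights and
#' pseudocounted frequencies; `glance()` returns a one-row model summary.
#'
#' @param x A `pwm_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pwm_model <- function(x, ...) {
  W <- x$width
  tibble::tibble(position = rep(seq_len(W), each = 4),
                 base = rep(DNA_BASES, W),
                 count = as.vector(x$counts),
                 weight = as.vector(x$weights),
                 freq = as.vector(column_freqs(x)))
}

#' @rdname tidy.pwm_model
#' @exportS3Method generics::glance
glance.pwm_model <- function(x, ...) {
  tibble::tibble(width = x$width, n_training = length(x$training_sites),
                 palindromic = x$palindromic, pseudocount = x$pseudocount,
                 threshold = x$threshold,
                 total_ic = sum(information_content(x)))
}

#' Sequence-logo style plot of a motif model
#'
#' Stacked per-position base frequencies scaled by the column information
#' content, the usual logo presentation.
#'
#' @param object A `pwm_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pwm_model <- function(object, ...) {
  ic <- information_content(object)
  df <- logo_table(object) |>
    dplyr::mutate(bits = .data$freq * ic[.data$position]) |>
    dplyr::arrange(.data$position, .data$freq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9, colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "motif position", y = "information (bits)", fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Serialize a motif model to TSV + JSON sidecar
#'
#' The TSV holds the count matrix (one row per motif position, columns
#' A,C,G,T); the JSON sidecar records width, palindromic flag, pseudocount,
#' threshold, and the training sites, so [read_motif()] reproduces the model
#' exactly.
#'
#' @param model A `pwm_model`.
#' @param tsv_path Output TSV path; the sidecar replaces the extension with
#'   `.json` unless `json_path` is given.
#' @param json_path Optional sidecar path.
#' @return Invisibly, `tsv_path`.
#' @export
write_motif <- function(model, tsv_path, json_path = NULL) {
  stopifnot(inherits(model, "pwm_model"))
  json_path <- json_path %||% paste0(tools::file_path_sans_ext(tsv_path), ".json")
  mat <- tibble::as_tibble(t(model$counts))
  readr::write_tsv(mat, tsv_path, progress = FALSE)
  meta <- list(width = model$width, palindromic = model$palindromic,
               pseudocount = model$pseudocount,
               threshold = if (is.na(model$threshold)) NULL else model$threshold,
               training_sites = model$training_sites)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' @rdname write_motif
#' @export
read_motif <- function(tsv_path, json_path = NULL) {
  json_path <- json_path %||% paste0(tools::file_path_sans_ext(tsv_path), ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  mat <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  counts <- t(as.matrix(mat[DNA_BASES]))
  dimnames(counts) <- list(DNA_BASES, NULL)
  model <- structure(list(width = as.integer(meta$width), counts = counts,
                          weights = counts_to_weights(counts, meta$pseudocount),
                          palindromic = isTRUE(meta$palindromic),
                          pseudocount = meta$pseudocount,
                          threshold = meta$threshold %||% NA_real_,
                          training_sites = meta$training_sites %||% character()),
                     class = "pwm_model")
  model
}

#' Import a MEME minimal-format motif as a count model
#'
#' Reads the first motif of a MEME minimal text file and converts its
#' letter-probability matrix to counts at a stated effective number of
#' sites (`nsites` from the file when present, else `effective_n`).
#'
#' @param path MEME minimal format file.
#' @param effective_n Fallback effective site count.
#' @param palindromic,pseudocount Passed to the resulting model.
#' @return A `pwm_model` (no training sites; threshold unset).
#' @export
read_meme_motif <- function(path, effective_n = 20, palindromic = FALSE,
                            pseudocount = 0.5) {
  lines <- readLines(path)
  mstart <- grep("^letter-probability matrix", lines)
  if (length(mstart) == 0) stop("no letter-probability matrix found", call. = FALSE)
  hdr <- lines[mstart[1]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  n <- if (grepl("nsites=", hdr)) as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else effective_n
  rows <- lines[(mstart[1] + 1):(mstart[1] + w)]
  probs <- t(vapply(rows, function(l) scan(text = l, quiet = TRUE), numeric(4),
                    USE.NAMES = FALSE))
  counts <- t(probs) * n
  dimnames(counts) <- list(DNA_BASES, NULL)
  if (palindromic) {
    counts <- (counts + counts[4:1, rev(seq_len(w)), drop = FALSE]) / 2
  }
  structure(list(width = w, counts = counts,
                 weights = counts_to_weights(counts, pseudocount),
                 palindromic = palindromic, pseudocount = pseudocount,
                 threshold = NA_real_, training_sites = character()),
            class = "pwm_model")
}
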