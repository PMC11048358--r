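#' Specification of a synthetic windows dataset
#'
#' The generator emulates the class-discriminating structure seen in
#' real pseudouridine benchmarks: fixed-length uridine-centered windows
#' in which a handful of positions near the center carry
#' class-dependent nucleotide enrichment (e.g. A/U favored at +1 in
#' sites, C/G at +1 in non-sites), with every other position drawn from
#' a common background. Positions are sampled independently given the
#' class; an optional first-order "stickiness" copies the previous base
#' with some probability, creating dinucleotide structure that marginal
#' (k = 1) features cannot see.
#'
#' @param window_length Odd window length `lambda` (21 or 31 typical).
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param enrichment Named list keyed by signed center offset (e.g.
#'   `"+1"`, `"-5"`; offset 0 is reserved for the fixed center U), each
#'   element a list with `pos` and `neg` probability 4-vectors over
#'   `(A, C, G, U)`.
#' @param background Probability 4-vector used at all other positions.
#' @param markov_stickiness Length-2 numeric `(pos, neg)`: probability
#'   of copying the previous base instead of the position draw
#'   (default 0 = fully independent positions).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(window_length = 21, n_pos = 200, n_neg = 200,
                           enrichment = list(),
                           background = rep(0.25, 4),
                           markov_stickiness = c(pos = 0, neg = 0),
                           seed = 1L) {
  if (window_length %% 2 == 0 || window_length < 3) {
    abort("window_length must be odd and >= 3.")
  }
  check_p <- function(p, what) {
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0(what, " must be a nonnegative 4-vector summing to 1."))
    }
  }
  check_p(background, "background")
  if (length(markov_stickiness) != 2 ||
      any(markov_stickiness < 0 | markov_stickiness > 1)) {
    abort("markov_stickiness must be two probabilities (pos, neg).")
  }
  if (is.null(names(markov_stickiness))) {
    names(markov_stickiness) <- c("pos", "neg")
  }
  half <- (window_length - 1) / 2
  for (off in names(enrichment)) {
    o <- as.integer(off)
    if (is.na(o) || o == 0 || abs(o) > half) {
      abort(paste0(
        "Enrichment offset ", off,
        " must be a nonzero integer within +/-", half, "."
      ))
    }
    check_p(enrichment[[off]]$pos, paste0("enrichment[['", off, "']]$pos"))
    check_p(enrichment[[off]]$neg, paste0("enrichment[['", off, "']]$neg"))
  }
  structure(
    list(window_length = as.integer(window_length),
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         enrichment = enrichment, background = background,
         markov_stickiness = markov_stickiness, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# 4 x lambda per-position probability matrix for one class
class_prob_matrix <- function(spec, class = c("pos", "neg")) {
  class <- match.arg(class)
  lambda <- spec$window_length
  center <- (lambda + 1) / 2
  P <- matrix(spec$background, 4, lambda)
  for (off in names(spec$enrichment)) {
    P[, center + as.integer(off)] <- spec$enrichment[[off]][[class]]
  }
  P[, center] <- c(0, 0, 0, 1)  # center base is always U
  rownames(P) <- BASES
  P
}

#' Generate a synthetic windows dataset
#'
#' Draws `n_pos` positive and `n_neg` negative windows from a
#' [synthetic_spec()], deterministic per seed. Every window's center
#' base is `U` and labels ride along, so the output feeds directly into
#' [fit_pseu()] or [write_rna_windows()].
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled `pseu_windows` tibble (positives first).
#' @export
generate_windows <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lambda <- spec$window_length
  center <- (lambda + 1) / 2
  draw_class <- function(n, class) {
    if (n == 0) return(character(0))
    P <- class_prob_matrix(spec, class)
    m <- matrix("", n, lambda)
    for (p in seq_len(lambda)) {
      m[, p] <- sample(BASES, n, replace = TRUE, prob = P[, p])
    }
    s <- spec$markov_stickiness[[class]]
    if (s > 0) {
      for (p in seq(2, lambda)) {
        if (p == center) next
        copy <- runif(n) < s
        m[copy, p] <- m[copy, p - 1]
      }
    }
    m[, center] <- "U"
    apply(m, 1, paste, collapse = "")
  }
  pos <- draw_class(spec$n_pos, "pos")
  neg <- draw_class(spec$n_neg, "neg")
  rna_windows(tibble(
    id = c(sprintf("pos_%04d", seq_along(pos)),
           sprintf("neg_%04d", seq_along(neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(length(pos), length(neg)))
  ))
}

#' Named synthetic presets
#'
#' Two fictitious-but-plausible enrichment layouts at benchmark window
#' lengths, with a single `strength` dial blending the motif with the
#' uniform background (`strength = 0` gives a null dataset with no
#' class signal; `strength = 1` the full motif):
#'
#' * `"human_like"` (`lambda = 21`): positives favor A/U at offsets -1
#'   and +1, negatives favor C/G there, with milder U-at--5 and
#'   C-at-+9 enrichment in negatives.
#' * `"yeast_like"` (`lambda = 31`): positives favor G/U upstream
#'   (-7, -3) and C/G downstream (+3, +7); negatives mildly favor
#'   A/C/U at -5 and +5.
#'
#' @param name Preset name.
#' @param n_pos,n_neg Class sizes (balanced 200 + 200 by default,
#'   matching the balanced benchmarks this emulates).
#' @param strength Motif strength in `[0, 1]`; the default 1 uses the
#'   stated enrichment probabilities as-is.
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
preset_spec <- function(name = c("human_like", "yeast_like"),
                        n_pos = 200, n_neg = 200, strength = 1,
                        seed = 1L) {
  name <- match.arg(name)
  stopifnot(strength >= 0, strength <= 1)
  blend <- function(p) strength * p + (1 - strength) * rep(0.25, 4)
  au <- c(0.45, 0.05, 0.05, 0.45)  # (A, C, G, U)
  cg <- c(0.05, 0.45, 0.45, 0.05)
  gu <- c(0.05, 0.05, 0.45, 0.45)
  unif <- rep(0.25, 4)
  enr <- if (name == "human_like") {
    list(
      "-1" = list(pos = blend(au), neg = blend(cg)),
      "+1" = list(pos = blend(au), neg = blend(cg)),
      "-5" = list(pos = unif, neg = blend(c(0.15, 0.15, 0.15, 0.55))),
      "+9" = list(pos = unif, neg = blend(c(0.15, 0.55, 0.15, 0.15)))
    )
  } else {
    list(
      "-7" = list(pos = blend(gu), neg = unif),
      "-3" = list(pos = blend(gu), neg = unif),
      "+3" = list(pos = blend(cg), neg = unif),
      "+7" = list(pos = blend(cg), neg = unif),
      "-5" = list(pos = unif, neg = blend(c(0.30, 0.30, 0.10, 0.30))),
      "+5" = list(pos = unif, neg = blend(c(0.30, 0.30, 0.10, 0.30)))
    )
  }
  synthetic_spec(
    window_length = if (name == "human_like") 21 else 31,
    n_pos = n_pos, n_neg = n_neg, enrichment = enr, seed = seed
  )
}

#' Both presets at their defaults
#'
#' @return Named list of [synthetic_spec()] objects (`human_like`,
#'   `yeast_like`).
#' @export
default_specs <- function() {
  list(human_like = preset_spec("human_like"),
       yeast_like = preset_spec("yeast_like"))
}
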