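#' G-test against a 50:50 null with Williams' correction
#'
#' Likelihood-ratio goodness-of-fit test of two counts against equal
#' expectation: `G = 2 * sum(O * log(O / E))` with `E = n/2` and
#' `0 * log(0) = 0`. Williams' small-sample correction divides G by
#' `q = 1 + (k^2 - 1) / (6 n (k - 1))`, which for `k = 2` cells is
#' `q = 1 + 1/(2n)`; the corrected statistic is compared to the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param counts integer vector of length 2, `c(n_a, n_b)`.
#' @return list of class `g_test`: `g`, `q`, `g_adjusted`, `p`, `n`.
#' @examples
#' g_test_williams(c(66, 34))
#' @export
g_test_williams <- function(counts) {
  stopifnot(length(counts) == 2L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no events")
  e <- n / 2
  terms <- ifelse(counts == 0, 0, counts * log(counts / e))
  g <- 2 * sum(terms)
  q <- 1 + 1 / (2 * n)
  g_adj <- g / q
  structure(list(g = g, q = q, g_adjusted = g_adj,
                 p = stats::pchisq(g_adj, df = 1, lower.tail = FALSE), n = n),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("<g_test: G = %.4f, Williams q = %.4f, G_adj = %.4f, p = %.4g (n = %d)>\n",
              x$g, x$q, x$g_adjusted, x$p, x$n))
  invisible(x)
}

#' Construct an operant keypeck log
#'
#' Events are keypecks on the left or right operant key over a 4-day test;
#' the stimulus assigned to each key switches every night to control for
#' side bias.
#'
#' @param events data.frame with columns `timestamp` (any orderable),
#'   `key` (`"left"`/`"right"`) and `day` (1--4).
#' @param assignment data.frame with columns `day`, `left_stimulus`,
#'   `right_stimulus` (values `"pre"`/`"post"`), one row per test day.
#' @return list of class `keypeck_log`.
#' @export
keypeck_log <- function(events, assignment) {
  stopifnot(all(c("timestamp", "key", "day") %in% names(events)),
            all(c("day", "left_stimulus", "right_stimulus") %in%
                  names(assignment)))
  if (!all(events$key %in% c("left", "right")))
    stop("key must be 'left' or 'right'")
  if (!all(events$day %in% assignment$day))
    stop("day without assignment")
  structure(list(events = events, assignment = assignment),
            class = "keypeck_log")
}

#' Analyse stimulus preference from a keypeck log
#'
#' Pools keypecks per stimulus over all test days using the nightly key
#' assignment, computes the preference for the focal stimulus (its keypecks
#' over total keypecks) and tests the pooled counts against the 50% chance
#' level with a Williams-corrected G-test.
#'
#' @param log a [keypeck_log].
#' @param focal the focal stimulus, default `"pre"`.
#' @param alpha significance level, default 0.05.
#' @return list of class `preference_result`: `n_pre`, `n_post`,
#'   `preference` (fraction for the focal stimulus), `g_statistic`,
#'   `williams_q`, `g_adjusted`, `p_value`, `significant`, `preferred`
#'   (`"pre"`, `"post"` or `"none"`).
#' @export
analyze_preference <- function(log, focal = c("pre", "post"), alpha = 0.05) {
  stopifnot(inherits(log, "keypeck_log"))
  focal <- match.arg(focal)
  i <- match(log$events$day, log$assignment$day)
  stim <- ifelse(log$events$key == "left",
                 as.character(log$assignment$left_stimulus[i]),
                 as.character(log$assignment$right_stimulus[i]))
  n_pre <- sum(stim == "pre"); n_post <- sum(stim == "post")
  gt <- g_test_williams(c(n_pre, n_post))
  n_focal <- if (focal == "pre") n_pre else n_post
  pref <- n_focal / (n_pre + n_post)
  sig <- gt$p < alpha
  preferred <- if (!sig) "none" else if (n_pre > n_post) "pre" else "post"
  structure(list(n_pre = n_pre, n_post = n_post, preference = pref,
                 g_statistic = gt$g, williams_q = gt$q,
                 g_adjusted = gt$g_adjusted, p_value = gt$p,
                 significant = sig, preferred = preferred, focal = focal),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf(paste0("<preference_result: %d pre / %d post pecks, ",
                     "preference(%s) = %.3f, G_adj = %.3f, p = %.4g, %s>\n"),
              x$n_pre, x$n_post, x$focal, x$preference, x$g_adjusted,
              x$p_value,
              if (x$significant) paste("prefers", x$preferred) else "ns"))
  invisible(x)
}

#' Select a duration- and source-level-matched stimulus motif pair
#'
#' From the pre and post motif tables, motifs within `duration_window` of the
#' condition's mean duration and `sl_window` of its mean source level are
#' eligible; one motif per condition is drawn uniformly at random (seeded).
#' If either eligible set is empty, both windows widen to the fallback
#' values (30 ms / 6 dB); if still empty, an error is raised.
#'
#' @param pre_motifs,post_motifs data.frames with columns `duration` (s) and
#'   `source_level` (dB).
#' @param duration_window duration window (s), default 0.004.
#' @param sl_window source-level window (dB), default 2.
#' @param fallback_duration_window,fallback_sl_window fallback windows,
#'   defaults 0.030 s and 6 dB.
#' @param seed RNG seed for the random draw.
#' @return list of class `stimulus_pair`: `selected_pre`, `selected_post`
#'   (row indices), `eligible_pre`, `eligible_post` (index vectors),
#'   `used_fallback`.
#' @export
select_stimulus_pair <- function(pre_motifs, post_motifs,
                                 duration_window = 0.004, sl_window = 2,
                                 fallback_duration_window = 0.030,
                                 fallback_sl_window = 6, seed = 1L) {
  eligible <- function(m, dw, sw) {
    which(abs(m$duration - mean(m$duration)) <= dw &
            abs(m$source_level - mean(m$source_level)) <= sw)
  }
  ep <- eligible(pre_motifs, duration_window, sl_window)
  eq <- eligible(post_motifs, duration_window, sl_window)
  used_fallback <- FALSE
  if (length(ep) == 0L || length(eq) == 0L) {
    used_fallback <- TRUE
    ep <- eligible(pre_motifs, fallback_duration_window, fallback_sl_window)
    eq <- eligible(post_motifs, fallback_duration_window, fallback_sl_window)
  }
  if (length(ep) == 0L || length(eq) == 0L) stop("no matched motifs")
  rng <- .seeded_rng(seed)
  sel_pre <- if (length(ep) == 1L) ep else rng$sample(ep, 1L)
  sel_post <- if (length(eq) == 1L) eq else rng$sample(eq, 1L)
  structure(list(selected_pre = sel_pre, selected_post = sel_post,
                 eligible_pre = ep, eligible_post = eq,
                 used_fallback = used_fallback),
            class = "stimulus_pair")
}

# Local, restorable RNG: runs `sample`/draws under the given seed without
# disturbing the caller's RNG state.
.seeded_rng <- function(seed) {
  list(sample = function(x, size) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(x, size)
  })
}
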