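#' Sohncke space groups
#'
#' The 65 Sohncke space groups: those containing only proper symmetry
#' operations (rotations and translations). Enantiopure chiral molecules can
#' only crystallise in these groups, which is enforced by the synthetic data
#' generator and exposed for downstream filtering.
#'
#' @return Integer vector of the 65 Sohncke space-group numbers (subset of
#'   1--230), sorted increasingly.
#' @export
#' @examples
#' length(sohncke_groups())  # 65
#' is_sohncke(c(14, 19))     # FALSE TRUE
sohncke_groups <- function() {
  c(1L,
    3L, 4L, 5L,
    16:24,
    75:80,
    89:98,
    143:146,
    149:155,
    168:173,
    177:182,
    195:199,
    207:214)
}

#' @rdname sohncke_groups
#' @param number integer vector of space-group numbers (1--230).
#' @export
is_sohncke <- function(number) {
  stopifnot(is.numeric(number), all(number >= 1), all(number <= 230))
  as.integer(number) %in% sohncke_groups()
}

#' Space-group label descriptor
#'
#' @param number integer space-group number in 1--230.
#' @return A list with fields `number` and `sohncke`.
#' @export
space_group_label <- function(number) {
  number <- as.integer(number)
  if (length(number) != 1L || is.na(number) || number < 1L || number > 230L) {
    stop("space-group number must be a single integer in 1..230")
  }
  list(number = number, sohncke = is_sohncke(number))
}

# Synthetic, CSD-like default label marginal over 25 space groups.
# The shape (a handful of dominant groups -- P2_1/c (14), P-1 (2),
# P2_12_12_1 (19), C2/c (15), P2_1 (4) -- followed by a long tail) mimics the
# well-known uneven space-group frequencies of organic molecular crystals.
# The numeric values are synthetic defaults, not database counts.
.default_marginal_25 <- function() {
  p <- c(`14` = 0.345, `2` = 0.245, `19` = 0.078, `15` = 0.082, `4` = 0.055,
         `61` = 0.035, `33` = 0.027, `9` = 0.022, `29` = 0.018, `1` = 0.016,
         `60` = 0.011, `5` = 0.010, `13` = 0.009, `7` = 0.008, `18` = 0.007,
         `43` = 0.006, `88` = 0.005, `86` = 0.004, `148` = 0.004, `56` = 0.003,
         `41` = 0.003, `76` = 0.002, `96` = 0.002, `114` = 0.002, `147` = 0.001)
  p / sum(p)
}

#' Default synthetic space-group marginals
#'
#' A CSD-like uneven distribution over the `k` most frequent groups of the
#' package's synthetic default marginal (25 groups, dominated by the five
#' groups that dominate organic crystal structures). These are synthetic
#' defaults for the data generator, not measured database frequencies.
#'
#' @param k number of space groups to keep (1--25); the marginal is
#'   renormalised over the `k` most probable groups.
#' @return Named numeric vector (names = space-group numbers) summing to 1.
#' @export
default_label_marginal <- function(k = 25) {
  p <- .default_marginal_25()
  stopifnot(k >= 1, k <= length(p))
  p <- sort(p, decreasing = TRUE)[seq_len(k)]
  p <- p / sum(p)
  # stable order: decreasing probability, ties by space-group number
  p[order(-p, as.integer(names(p)))]
}
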