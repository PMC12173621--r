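# Sensory texture statistics: questionnaire scoring, Likert panel
# summaries, per-feature one-way ANOVA, and Spearman rank correlation with
# an exact permutation null at small n.

.FEATURES <- c("soft", "hard", "brittle", "chewy", "gummy", "viscous",
               "springy", "sticky", "fibrous", "fatty", "moist", "meaty")

#' Texture features of the sensory survey
#'
#' The twelve texture descriptors rated on a 5-point Likert scale
#' ("this food is ..."): soft, hard, brittle, chewy, gummy, viscous,
#' springy, sticky, fibrous, fatty, moist, meaty.
#'
#' @return Character vector of feature names.
#' @export
texture_features <- function() .FEATURES

#' Validate a Likert texture table
#'
#' @param data data frame with columns `participant`, `product`, `feature`,
#'   `score` (integers on the given scale).
#' @param scale_points number of scale points (default 5).
#' @return The validated data frame, class `likert_table`.
#' @export
likert_table <- function(data, scale_points = 5) {
  need <- c("participant", "product", "feature", "score")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("likert table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!data$score %in% seq_len(scale_points))
  if (length(bad))
    stop("score out of the 1..", scale_points, " scale at row ", bad[1],
         " (participant ", data$participant[bad[1]], ")", call. = FALSE)
  counts <- table(data$participant, data$product)
  if (length(unique(counts[counts > 0])) > 1)
    warning("incomplete cases: participants rate unequal numbers of ",
            "features per product", call. = FALSE)
  structure(data, scale_points = scale_points,
            class = unique(c("likert_table", class(data))))
}

#' Validated questionnaire instruments
#'
#' Metadata for the two companion questionnaires: the ten-item, 7-point
#' food-neophobia survey (totals range 10 = neophilic to 70 = neophobic)
#' and the sixteen-item, 5-point meat-attachment questionnaire (16 = not
#' attached to 80 = very attached). `reverse_items` defaults to the
#' standard key for the neophobia survey (items 1, 4, 6, 9, 10 are worded
#' against neophobia). The meat-attachment questionnaire's reverse-worded
#' aversion items depend on the item order of the administered form, so no
#' default is assumed; pass their positions explicitly.
#'
#' @param name `"neophobia"` or `"meat_attachment"`.
#' @param reverse_items integer positions of reverse-coded items;
#'   overrides the default key.
#' @return List of class `instrument` with `name`, `n_items`,
#'   `scale_points`, `reverse_items` and `score_range`.
#' @export
instrument <- function(name = c("neophobia", "meat_attachment"),
                       reverse_items = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
                 neophobia = list(n_items = 10L, scale_points = 7L,
                                  reverse = c(1L, 4L, 6L, 9L, 10L)),
                 meat_attachment = list(n_items = 16L, scale_points = 5L,
                                        reverse = integer(0)))
  reverse <- reverse_items %||% spec$reverse
  stopifnot(all(reverse %in% seq_len(spec$n_items)))
  structure(list(name = name, n_items = spec$n_items,
                 scale_points = spec$scale_points,
                 reverse_items = as.integer(reverse),
                 score_range = c(spec$n_items,
                                 spec$n_items * spec$scale_points)),
            class = "instrument")
}

#' Score questionnaire responses
#'
#' Reverse-coded items are reflected (`x` becomes `scale_points + 1 - x`)
#' and item responses summed per participant. Totals are guaranteed to lie
#' in the instrument's score range.
#'
#' @param responses data frame with columns `participant`, `item`,
#'   `response`.
#' @param instr an [instrument()].
#' @return Named numeric vector of totals, one per participant.
#' @examples
#' instr <- instrument("neophobia")
#' r <- expand.grid(participant = "p1", item = 1:10)
#' r$response <- 7
#' score_instrument(r, instr)   # 70, the neophobic extreme
#' @export
score_instrument <- function(responses, instr) {
  stopifnot(inherits(instr, "instrument"))
  need <- c("participant", "item", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!responses$response %in% seq_len(instr$scale_points) |
                 !responses$item %in% seq_len(instr$n_items))
  if (length(bad))
    stop("out-of-scale response at row ", bad[1], " (participant ",
         responses$participant[bad[1]], ", item ", responses$item[bad[1]],
         ")", call. = FALSE)
  x <- responses$response
  rev <- responses$item %in% instr$reverse_items
  x[rev] <- instr$scale_points + 1L - x[rev]
  totals <- tapply(x, responses$participant, sum)
  n_items <- tapply(x, responses$participant, length)
  if (any(n_items != instr$n_items))
    stop("each participant must answer all ", instr$n_items, " items",
         call. = FALSE)
  stats::setNames(as.numeric(totals), names(totals))
}

#' Per-product, per-feature Likert summary
#'
#' @param table a [likert_table()].
#' @return Data frame with `product`, `feature`, `mean`, `sd`, `n`.
#' @export
summarize_features <- function(table) {
  agg <- stats::aggregate(score ~ product + feature, data = table,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(product = agg$product, feature = agg$feature,
                    mean = agg$score[, "mean"], sd = agg$score[, "sd"],
                    n = agg$score[, "n"])
  out[order(out$feature, -out$mean), ]
}

#' One-way ANOVA across products for one texture feature
#'
#' Plain one-way ANOVA treating the Likert scores as interval data and
#' participants as independent observations, with significance at
#' p < 0.05.
#'
#' @param table a [likert_table()].
#' @param feature one feature name.
#' @param alpha significance level.
#' @return List with `F`, `df`, `p_value`, `significant`, `degenerate`.
#' @export
feature_anova <- function(table, feature, alpha = 0.05) {
  sub <- table[table$feature == feature, ]
  if (!nrow(sub)) stop("no rows for feature: ", feature, call. = FALSE)
  if (length(unique(sub$product)) < 2 || min(table(sub$product)) < 2)
    stop("need at least 2 products with at least 2 scores each",
         call. = FALSE)
  if (stats::sd(sub$score) == 0)
    return(list(F = NA_real_, df = c(NA_real_, NA_real_),
                p_value = NA_real_, significant = FALSE, degenerate = TRUE))
  aovfit <- stats::aov(score ~ factor(product), data = sub)
  tab <- summary(aovfit)[[1]]
  list(F = tab[["F value"]][1], df = tab[["Df"]],
       p_value = tab[["Pr(>F)"]][1],
       significant = isTRUE(tab[["Pr(>F)"]][1] < alpha), degenerate = FALSE)
}

# All n! permutations of 1..n as an (n! x n) integer matrix, built
# iteratively by inserting element k into every position of each
# permutation of k-1 elements.
all_permutations <- function(n) {
  P <- matrix(1L, 1, 1)
  if (n == 1) return(P)
  for (k in 2:n) {
    nr <- nrow(P)
    out <- matrix(0L, nr * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * nr + seq_len(nr)
      out[rows, pos] <- k
      out[rows, -pos] <- P
    }
    P <- out
  }
  P
}

#' Spearman rank correlation with exact permutation p-value
#'
#' The coefficient is the Pearson correlation of midranks (equivalent to
#' `1 - 6*sum(d^2)/(n(n^2-1))` without ties). For `n <= 10` the two-sided
#' p-value is computed exactly by enumerating all `n!` permutations of one
#' variable's ranks; larger samples use the t approximation with `n - 2`
#' degrees of freedom. The permutation null is enumerated in chunks over
#' the first rank position, keeping memory modest at `n = 10`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"auto"` (exact for `n <= 10`), `"exact"`, or
#'   `"approx"`.
#' @return List of class `spearman_cor` with `rho`, `p_value`, `method`,
#'   `n`.
#' @examples
#' spearman_cor(1:8, c(2, 1, 3, 4, 6, 5, 8, 7))
#' @export
spearman_cor <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || n < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not supported", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= 10) "exact" else "approx"
  if (method == "exact") {
    if (n > 10)
      stop("exact enumeration is limited to n <= 10", call. = FALSE)
    # rho is affine in S = sum(rx * permuted ry); enumerate S over S_n
    sdprod <- stats::sd(rx) * stats::sd(ry)
    mterm <- n * mean(rx) * mean(ry)
    rho_from_S <- function(S) ((S - mterm) / (n - 1)) / sdprod
    if (n <= 8) {
      # permute ry against fixed rx; only S varies across permutations
      P <- all_permutations(n)
      S <- as.vector(matrix(ry[P], nrow(P), n) %*% rx)
      count <- sum(abs(rho_from_S(S)) >= abs(rho) - 1e-12)
      total <- nrow(P)
    } else {
      # chunk over the first position to bound memory
      Psub <- all_permutations(n - 1)
      count <- 0; total <- 0
      for (j in seq_len(n)) {
        others <- setdiff(seq_len(n), j)
        idx <- matrix(others[Psub], nrow(Psub), n - 1)
        S <- ry[j] * rx[1] +
          as.vector(matrix(ry[idx], nrow(idx), n - 1) %*% rx[-1])
        count <- count + sum(abs(rho_from_S(S)) >= abs(rho) - 1e-12)
        total <- total + nrow(Psub)
      }
    }
    p <- count / total
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = min(1, p),
                 method = if (method == "exact") "exact_permutation"
                          else "t_approximation", n = n),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (%s, n = %d)\n",
              x$rho, x$p_value, x$method, x$n))
  invisible(x)
}

#' Stiffness-texture correlation matrix
#'
#' Pairwise Spearman correlations among physical stiffness and the
#' (ANOVA-significant) sensory features, computed on per-product feature
#' means. Pairs with p below the significance level are flagged with their
#' sign. No multiple-testing correction is applied.
#'
#' @param stiffness named numeric vector of per-product stiffness (kPa),
#'   e.g. the neo-Hookean `E` of each product.
#' @param feature_summaries output of [summarize_features()].
#' @param features which features to include; defaults to all present.
#' @param alpha significance level for flagging.
#' @return List with `rho` and `p` matrices, and `significant_pairs`
#'   (data frame `var1`, `var2`, `rho`, `p_value`, `sign`).
#' @export
stiffness_texture_correlations <- function(stiffness, feature_summaries,
                                           features = NULL, alpha = 0.05) {
  if (is.null(names(stiffness)))
    stop("stiffness must be a named vector (names = product ids)",
         call. = FALSE)
  features <- features %||% unique(feature_summaries$feature)
  products <- names(stiffness)
  vars <- list(stiffness = stiffness[products])
  for (f in features) {
    sub <- feature_summaries[feature_summaries$feature == f, ]
    m <- stats::setNames(sub$mean, sub$product)
    if (!all(products %in% names(m)))
      stop("feature ", f, " is missing products: ",
           paste(setdiff(products, names(m)), collapse = ", "),
           call. = FALSE)
    vars[[f]] <- m[products]
  }
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(names(vars),
                                                     names(vars)))
  diag(rho) <- 1; diag(p) <- 0
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sc <- spearman_cor(vars[[i]], vars[[j]])
    rho[i, j] <- rho[j, i] <- sc$rho
    p[i, j] <- p[j, i] <- sc$p_value
    if (sc$p_value < alpha)
      pairs[[length(pairs) + 1]] <-
        data.frame(var1 = names(vars)[i], var2 = names(vars)[j],
                   rho = sc$rho, p_value = sc$p_value,
                   sign = ifelse(sc$rho >= 0, "positive", "negative"))
  }
  list(rho = rho, p = p,
       significant_pairs = if (length(pairs)) do.call(rbind, pairs)
       else data.frame(var1 = character(0), var2 = character(0),
                       rho = numeric(0), p_value = numeric(0),
                       sign = character(0)))
}
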