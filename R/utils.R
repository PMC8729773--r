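# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero
#' (the convention used for reported percentages; base `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a reproducible sub-seed below 2^31 from a base seed and a stream index
.sub_seed <- function(seed, stream) {
  (as.integer(seed) + 7919L * as.integer(stream)) %% 2147483647L
}

.assert_count_matrix <- function(x, what = "table") {
  if (!is.matrix(x)) stop(what, " must be a matrix (samples x OTUs)")
  if (any(is.na(x))) stop(what, " contains missing values")
  if (any(x < 0)) stop(what, " contains negative values")
  invisible(x)
}

# compact multiple-comparison letter display from a logical "differs" matrix
.letter_display <- function(diff_mat) {
  g <- rownames(diff_mat)
  n <- length(g)
  # insert-and-absorb: start with one letter containing everyone, split on conflicts
  groups <- list(seq_len(n))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!diff_mat[i, j]) next
      for (k in seq_along(groups)) {
        if (i %in% groups[[k]] && j %in% groups[[k]]) {
          groups[[k]] <- setdiff(groups[[k]], j)
          groups[[length(groups) + 1]] <- setdiff(union(groups[[k]], j), i)
        }
      }
      # absorb duplicates/subsets
      keep <- rep(TRUE, length(groups))
      for (k in seq_along(groups)) {
        for (l in seq_along(groups)) {
          if (k != l && keep[l] && all(groups[[k]] %in% groups[[l]]) &&
              length(groups[[k]]) < length(groups[[l]])) keep[k] <- FALSE
        }
      }
      groups <- groups[keep]
    }
  }
  letters_out <- character(n)
  for (k in seq_along(groups)) {
    for (i in groups[[k]]) letters_out[i] <- paste0(letters_out[i], letters[k])
  }
  stats::setNames(letters_out, g)
}
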