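# Symmetric similarity matrices shared across modules.

new_similarity <- function(m, value_kind, ...) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(list(matrix = m, value_kind = value_kind, extra = list(...)),
            class = "zf_similarity")
}

unclass_sim <- function(x) {
  if (inherits(x, "zf_similarity")) x$matrix else as.matrix(x)
}

#' @export
print.zf_similarity <- function(x, ...) {
  cat(sprintf("<zf_similarity> %d x %d, value_kind = %s\n",
              nrow(x$matrix), ncol(x$matrix), x$value_kind))
  print(utils::head(round(x$matrix, 3), 6))
  invisible(x)
}

#' @export
as.matrix.zf_similarity <- function(x, ...) x$matrix

#' Tidy a similarity matrix into one row per entity pair
#'
#' @param x A `zf_similarity` object.
#' @param ... Unused.
#' @return Tibble with columns `a`, `b`, `value` covering the upper triangle.
#' @method tidy zf_similarity
#' @export
tidy.zf_similarity <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(a = rownames(m)[idx[, 1]], b = colnames(m)[idx[, 2]],
         value = m[idx])
}

#' @method glance zf_similarity
#' @export
glance.zf_similarity <- function(x, ...) {
  v <- x$matrix[upper.tri(x$matrix)]
  tibble(n_entities = nrow(x$matrix), value_kind = x$value_kind,
         mean = mean(v), median = stats::median(v), max = max(v))
}

#' Heat-map of a similarity matrix
#'
#' @param object A `zf_similarity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zf_similarity
#' @export
autoplot.zf_similarity <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(a = rownames(m), b = colnames(m))
  df$value <- m[cbind(df$a, df$b)]
  df$a <- factor(df$a, levels = rownames(m))
  df$b <- factor(df$b, levels = rev(colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$value_kind) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# Convert a similarity object/matrix to a distance matrix (1 - similarity).
#' Distance matrix from a similarity matrix
#'
#' @param sim A `zf_similarity` object or plain symmetric matrix.
#' @return A symmetric matrix with zero diagonal.
#' @export
similarity_to_distance <- function(sim) {
  m <- 1 - unclass_sim(sim)
  diag(m) <- 0
  m
}
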