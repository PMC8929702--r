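## Nested-effects model matrix: intercept, genetic-background main effects,
## and environment effects nested within background. There is deliberately
## no environment main-effect term: an environment shift is always read
## relative to the background the library was made in.

#' Build the nested-effects design matrix
#'
#' Encodes the model `E(y | x) = exp(b0 + x_g b_g + x_{e|g} b_{e|g})`:
#' one intercept, one indicator per non-reference genetic background, and
#' one indicator per (background, non-control environment) pair. The
#' control background is the reference background and the control
#' environment is the reference environment within every background.
#' Column order is deterministic: intercept, backgrounds sorted, then
#' nested pairs sorted by (background, environment).
#'
#' @param samples sample metadata data frame (see [validate_sample_meta()]).
#' @param control length-2 character vector `c(background, environment)`
#'   naming the control condition; it must occur among the samples.
#' @return A numeric matrix of class `nested_design` (rows follow
#'   `samples`), with attributes `labels` (data frame with `kind`,
#'   `background`, `environment` per column) and `control`.
#' @export
build_design <- function(samples, control) {
  samples <- validate_sample_meta(samples, control = control)
  gs <- sort(unique(samples$background))
  es <- sort(unique(samples$environment))
  g0 <- control[[1]]
  e0 <- control[[2]]
  other_g <- setdiff(gs, g0)
  other_e <- setdiff(es, e0)
  n <- nrow(samples)
  labels <- data.frame(kind = "intercept", background = NA_character_,
                       environment = NA_character_, stringsAsFactors = FALSE)
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  for (g in other_g) {
    X <- cbind(X, as.numeric(samples$background == g))
    colnames(X)[ncol(X)] <- paste0("bg:", g)
    labels <- rbind(labels, data.frame(kind = "background", background = g,
                                       environment = NA_character_))
  }
  for (g in gs) for (e in other_e) {
    X <- cbind(X, as.numeric(samples$background == g & samples$environment == e))
    colnames(X)[ncol(X)] <- paste0("env:", e, "|", g)
    labels <- rbind(labels, data.frame(kind = "nested", background = g,
                                       environment = e))
  }
  rownames(X) <- samples$sample_id
  structure(X, labels = labels, control = c(background = g0, environment = e0),
            class = c("nested_design", "matrix", "array"))
}

#' @export
print.nested_design <- function(x, ...) {
  lab <- attr(x, "labels")
  cat("Nested design:", nrow(x), "samples x", ncol(x), "columns\n")
  cat("  backgrounds:", sum(lab$kind == "background"),
      " nested condition terms:", sum(lab$kind == "nested"), "\n")
  ctl <- attr(x, "control")
  cat("  control: (", ctl[["background"]], ", ", ctl[["environment"]], ")\n", sep = "")
  invisible(x)
}

## Strip the nested_design class so plain matrix algebra applies.
design_matrix <- function(X) {
  if (inherits(X, "nested_design")) unclass(X)[, , drop = FALSE] else as.matrix(X)
}
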