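## Internal helpers: validation, RNG scoping, small utilities.

#' @keywords internal
#' @importFrom stats simulate coef fitted logLik predict residuals
#' @importFrom graphics plot
"_PACKAGE"

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a reproducible sub-seed (kept below 2^31) from a master seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483647L)
}

stop_validation <- function(...) {
  stop(structure(class = c("contness_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("contness_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

#' Validate a sample metadata table
#'
#' Checks that a sample-metadata data frame has the columns `sample_id`,
#' `background`, `environment` and `replicate`, that sample ids are unique,
#' and (when `control` is given) that at least one sample belongs to the
#' declared control (background, environment) pair.
#'
#' @param samples data frame of sample metadata.
#' @param control optional length-2 character vector
#'   `c(background, environment)` naming the control condition.
#' @return The validated data frame, invisibly coerced to character columns
#'   plus an integer `replicate`.
#' @export
validate_sample_meta <- function(samples, control = NULL) {
  need <- c("sample_id", "background", "environment", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_format("sample metadata is missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$background <- as.character(samples$background)
  samples$environment <- as.character(samples$environment)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop_validation("duplicate sample_id in sample metadata")
  if (any(!is.finite(samples$replicate)) || any(samples$replicate < 1))
    stop_validation("replicate must be a positive integer")
  if (!is.null(control)) {
    hit <- samples$background == control[[1]] & samples$environment == control[[2]]
    if (!any(hit))
      stop_validation("control condition (", control[[1]], ", ", control[[2]],
                      ") has no samples")
  }
  samples
}

#' Read sample metadata from a TSV file
#'
#' The file must be tab-separated with a header containing the columns
#' `sample_id`, `background`, `environment` and `replicate`.
#'
#' @param path path to the TSV file.
#' @param control optional control pair passed to [validate_sample_meta()].
#' @return A data frame of sample metadata.
#' @export
read_sample_meta <- function(path, control = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(df, control = control)
}

#' @rdname read_sample_meta
#' @param samples a validated sample-metadata data frame.
#' @export
write_sample_meta <- function(samples, path) {
  samples <- validate_sample_meta(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
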