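#' @importFrom stats rbinom runif rnbinom qnorm pnorm dnorm plogis qlogis
#'   rnorm optimize integrate kmeans hclust cutree as.dist cmdscale density
#'   var qt pt setNames aggregate rmultinom
#' @importFrom utils head modifyList
#' @importFrom rlang .data
#' @importFrom tools md5sum
NULL

# let [.data.table dispatch correctly although data.table is used via ::
.datatable.aware <- TRUE

# Derive independent substream seeds from one master seed. R's integers are
# 32-bit, so substreams are drawn (not multiplied) from the master stream.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression under a local, seeded RNG stream without disturbing the
# caller's stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the usual
#' half-up convention of clinical tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
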