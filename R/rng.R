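#' Seeded random streams
#'
#' A small handle around R's L'Ecuyer-CMRG generator providing
#' reproducible, spawnable random streams.  Identical seeds give
#' bitwise-identical draw sequences; [rng_spawn()] returns statistically
#' independent child streams (one per ring-polymer replica, cluster,
#' etc.) using the CMRG stream-jumping facility.
#'
#' The handle owns its own generator state: drawing from it never
#' disturbs (and is never disturbed by) the global \code{.Random.seed}.
#'
#' @param seed non-negative integer seed.
#' @return an object of class \code{mlcmd_rng}.
#' @examples
#' r <- seeded_rng(7)
#' rng_gauss(r, 3)
#' child <- rng_spawn(r)
#' rng_unif(child, 2)
#' @export
seeded_rng <- function(seed) {
  if (length(seed) != 1L || is.na(seed) || seed < 0 || seed != floor(seed))
    stop("seed must be a single non-negative integer")
  env <- new.env(parent = emptyenv())
  env$state <- local({
    save <- .save_global_rng()
    on.exit(.restore_global_rng(save))
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(as.integer(seed %% .Machine$integer.max))
    get(".Random.seed", envir = globalenv())
  })
  env$spawn_cursor <- env$state
  class(env) <- "mlcmd_rng"
  env
}

.save_global_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_global_rng <- function(save) {
  if (is.null(save)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", save, envir = globalenv())
}

# run a draw expression under the handle's state, then persist the
# advanced state back into the handle
.with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "mlcmd_rng"))
  save <- .save_global_rng()
  on.exit(.restore_global_rng(save))
  assign(".Random.seed", rng$state, envir = globalenv())
  out <- expr
  rng$state <- get(".Random.seed", envir = globalenv())
  out
}

#' @rdname seeded_rng
#' @param rng an \code{mlcmd_rng} handle.
#' @param n number of draws.
#' @export
rng_gauss <- function(rng, n) .with_rng(rng, stats::rnorm(n))

#' @rdname seeded_rng
#' @export
rng_unif <- function(rng, n) .with_rng(rng, stats::runif(n))

#' @rdname seeded_rng
#' @param max draws are integers in \code{1:max}.
#' @export
rng_int <- function(rng, n, max) .with_rng(rng, sample.int(max, n, replace = TRUE))

#' @rdname seeded_rng
#' @export
rng_spawn <- function(rng) {
  stopifnot(inherits(rng, "mlcmd_rng"))
  child_state <- parallel::nextRNGStream(rng$spawn_cursor)
  rng$spawn_cursor <- child_state
  env <- new.env(parent = emptyenv())
  env$state <- child_state
  env$spawn_cursor <- child_state
  class(env) <- "mlcmd_rng"
  env
}

# a 31-bit integer seed for compiled kernels, consumed from the stream
rng_kernel_seed <- function(rng) {
  as.integer(floor(rng_unif(rng, 1) * (.Machine$integer.max - 1))) + 1L
}

#' @export
print.mlcmd_rng <- function(x, ...) {
  cat("<mlcmd seeded RNG stream (L'Ecuyer-CMRG)>\n")
  invisible(x)
}
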