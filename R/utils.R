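#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rgamma rnorm runif rbinom pbinom phyper chisq.test
#'   wilcox.test p.adjust setNames median aggregate
#' @importFrom utils read.delim write.table head combn packageVersion str
NULL

.pkg_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master
#' integer so that a whole simulated study is reproducible from a single value,
#' while different stages use decorrelated streams.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 2654435 + h) %% 2147480009 + 1)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## small named-list -> data.frame helper for rule tables
rbind_dfs <- function(lst) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
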