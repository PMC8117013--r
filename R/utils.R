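#' Run code with a locally-set RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the prior RNG
#' state afterwards, so that generator functions are reproducible without
#' clobbering the caller's random stream. With `seed = NULL` the current
#' stream is used as-is.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific child seed from a base seed; keeps results
# decoupled across stages while remaining a pure function of (seed, label)
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

#' Stand composition types and chronology group labels
#'
#' The five chronology groups are species x stand-composition combinations:
#' black spruce in pure black spruce (PBS), mixed (M) and pure trembling
#' aspen (PTA) stands, and trembling aspen in PTA and M stands.
#'
#' @return character vector of the five group labels.
#' @export
chronology_groups <- function() {
  c("spruce_PBS", "spruce_M", "spruce_PTA", "aspen_PTA", "aspen_M")
}

group_species <- function(group) {
  ifelse(grepl("^spruce", group), "black_spruce", "trembling_aspen")
}

group_stand <- function(group) sub("^[a-z]+_", "", group)

stand_types <- function() c("PBS", "M", "PTA")
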