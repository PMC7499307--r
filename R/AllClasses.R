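#' @import methods
#' @importFrom stats median p.adjust pchisq phyper pnorm pt rlnorm rnbinom
#'   rnorm rpois runif sd var cor
#' @importFrom utils head read.delim write.table combn
NULL

#' Differential-expression result from the pooled permutation procedure
#'
#' Container for the per-gene output of [runPermutedDE()]: permutation-averaged
#' log2 fold changes (NP relative to AF), permutation-averaged \eqn{-\log_{10} p}
#' values, the back-transformed combined p value, Benjamini-Hochberg q values,
#' significance calls and direction labels, together with the parameters of the
#' run.
#'
#' @slot table `data.frame` with one row per tested gene and columns
#'   `gene`, `meanLog2FC`, `meanNegLog10P`, `combinedP`, `q`, `significant`,
#'   `direction` (`"NP-high"`, `"AF-high"` or `"none"`).
#' @slot params named list echoing the pooling parameters (pool size,
#'   permutations, FDR level, seed, normalization mode).
#' @slot nDropped number of genes removed before testing because they were
#'   expressed in zero cells.
#'
#' @seealso [runPermutedDE()], [deTable()], [significantGenes()]
#' @export
setClass("DEResult",
  representation(table = "data.frame", params = "list", nDropped = "numeric"),
  prototype(table = data.frame(), params = list(), nDropped = 0)
)

setValidity("DEResult", function(object) {
  tab <- object@table
  need <- c("gene", "meanLog2FC", "meanNegLog10P", "combinedP", "q",
            "significant", "direction")
  if (!all(need %in% names(tab))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(tab) > 0L) {
    if (anyDuplicated(tab$gene)) return("duplicate gene symbols in table")
    if (any(tab$combinedP < 0 | tab$combinedP > 1, na.rm = TRUE)) {
      return("combinedP outside [0,1]")
    }
    if (any(tab$q + 1e-12 < tab$combinedP, na.rm = TRUE)) {
      return("q must be >= combined p")
    }
  }
  TRUE
})

#' MCODE molecular complex
#'
#' One dense complex detected by [mcodeFindComplexes()]: its member genes, the
#' number of edges they induce in the parent network, the seed node it grew
#' from, and the MCODE score (subgraph density multiplied by the number of
#' member nodes).
#'
#' @slot members character vector of member gene symbols.
#' @slot nEdges number of edges induced by the members.
#' @slot score complex score, density x node count.
#' @slot seed the seed node the complex was grown from.
#' @export
setClass("McodeComplex",
  representation(members = "character", nEdges = "numeric",
                 score = "numeric", seed = "character")
)

setValidity("McodeComplex", function(object) {
  n <- length(object@members)
  if (n < 2L) return("a complex needs at least 2 members")
  if (anyDuplicated(object@members)) return("duplicate members")
  if (object@nEdges < 0 || object@nEdges > choose(n, 2)) {
    return("edge count incompatible with member count")
  }
  if (object@score > n + 1e-9) return("score cannot exceed the node count")
  TRUE
})

#' @describeIn DEResult compact display
#' @param object a `DEResult` or `McodeComplex`.
#' @export
setMethod("show", "DEResult", function(object) {
  tab <- object@table
  cat(sprintf("DEResult: %d genes tested (%d dropped as unexpressed)\n",
              nrow(tab), object@nDropped))
  cat(sprintf("  significant at q < %g: %d (%d NP-high, %d AF-high)\n",
              object@params$fdrAlpha %||% 0.05,
              sum(tab$significant),
              sum(tab$significant & tab$direction == "NP-high"),
              sum(tab$significant & tab$direction == "AF-high")))
  cat(sprintf("  pool size %s, %s permutations, seed %s\n",
              object@params$poolSize %||% "?",
              object@params$nPermutations %||% "?",
              object@params$seed %||% "?"))
})

#' @describeIn McodeComplex compact display
#' @export
setMethod("show", "McodeComplex", function(object) {
  cat(sprintf("McodeComplex: %d genes, %d interactions, score %.1f (seed %s)\n",
              length(object@members), object@nEdges, object@score,
              object@seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for DEResult and McodeComplex
#'
#' `deTable()` returns the per-gene result table; `significantGenes()` the
#' symbols called significant (optionally restricted to one direction);
#' `members()` and `complexScore()` the member genes and score of a complex.
#'
#' @param x a `DEResult` (for `deTable`, `significantGenes`) or an
#'   `McodeComplex` (for `members`, `complexScore`).
#' @param direction optional `"NP-high"` or `"AF-high"` filter.
#' @return `deTable`: a `data.frame`; `significantGenes`, `members`:
#'   character vectors; `complexScore`: a number.
#' @name de-accessors
NULL

#' @rdname de-accessors
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname de-accessors
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname de-accessors
#' @export
setGeneric("significantGenes",
           function(x, direction = NULL) standardGeneric("significantGenes"))

#' @rdname de-accessors
#' @export
setMethod("significantGenes", "DEResult", function(x, direction = NULL) {
  tab <- x@table[x@table$significant, , drop = FALSE]
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("NP-high", "AF-high"))
    tab <- tab[tab$direction == direction, , drop = FALSE]
  }
  tab$gene
})

#' @rdname de-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname de-accessors
#' @export
setMethod("members", "McodeComplex", function(x) x@members)

#' @rdname de-accessors
#' @export
setGeneric("complexScore", function(x) standardGeneric("complexScore"))

#' @rdname de-accessors
#' @export
setMethod("complexScore", "McodeComplex", function(x) x@score)
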