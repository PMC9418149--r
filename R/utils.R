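# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a private RNG stream, restoring the caller's RNG
# state afterwards. All stochastic entry points funnel through this so that
# results are bit-reproducible given an explicit seed and the global RNG is
# never disturbed.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed, keeping within 32-bit range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483587)
}

#' Parse diagnostic motif tokens
#'
#' A motif token is `"<anc><pos><der>"`, e.g. `"A281G"`: ancestral (reference)
#' base, 1-based reference position, derived base.
#'
#' @param tokens character vector of tokens.
#' @return data.frame with columns `position`, `ancestral`, `derived`,
#'   `token`, ordered as given.
#' @examples
#' parseMotifs(c("A281G", "T355C"))
#' @export
parseMotifs <- function(tokens) {
  ok <- grepl("^[ACGT][0-9]+[ACGT]$", tokens)
  if (!all(ok))
    stop("malformed motif token(s): ", paste(tokens[!ok], collapse = ", "))
  anc <- substr(tokens, 1L, 1L)
  der <- substring(tokens, nchar(tokens))
  pos <- as.integer(substr(tokens, 2L, nchar(tokens) - 1L))
  if (any(anc == der))
    stop("motif with identical ancestral and derived base: ",
         paste(tokens[anc == der], collapse = ", "))
  data.frame(position = pos, ancestral = anc, derived = der, token = tokens,
             stringsAsFactors = FALSE)
}

#' @rdname parseMotifs
#' @param position,ancestral,derived vectors defining substitutions.
#' @export
formatMotifs <- function(ancestral, position, derived) {
  paste0(ancestral, position, derived)
}

# p-value convention used by all permutation tests: the observed statistic
# counts as one permutation, so p is never exactly 0.
permPvalue <- function(nGreaterEq, nPerm) (nGreaterEq + 1) / (nPerm + 1)
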