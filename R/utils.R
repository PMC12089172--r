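#' @importFrom rlang %||%
#' @importFrom stats sd setNames pchisq fisher.test hclust dist cutree t.test
#' @importFrom utils head read.csv write.csv combn
NULL

# Case-fold, trim and collapse internal whitespace. Applied before every
# text-matching operation so that "  Own Car " and "own car" compare equal.
normalize_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# whitespace tokenization used by the word-count validation rule
count_words <- function(x) {
  vapply(strsplit(trimws(x), "[[:space:]]+"), function(w) sum(nzchar(w)), integer(1))
}

stop_camnet <- function(msg, class) {
  stop(rlang::error_cnd(class = c(class, "camnet_error"), message = msg))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# deterministic seed derivation below 2^31 for per-unit random streams
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + salt) %% 2147483647)
}
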