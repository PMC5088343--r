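#' Tokenize post text
#'
#' Splits text into lowercase tokens on whitespace, stripping leading and
#' trailing punctuation, except that a leading `#` or `@` is kept attached to
#' its token. Hashtags are deliberately *not* segmented into words, so
#' `"#runrunrun"` stays a single opaque token and will not match lexicon
#' entries — mirroring a documented failure mode of hashtag-heavy posts.
#'
#' @param text Character vector of post texts.
#' @return For a single string, a character vector of tokens; for a longer
#'   input, a list of token vectors (one per element).
#' @examples
#' tokenize("Running late!")
#' tokenize("#RunRunRun")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  out <- lapply(strsplit(tolower(text), "\\s+"), clean_tokens)
  if (length(text) == 1L) out[[1L]] else out
}

clean_tokens <- function(raw) {
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(character())
  # trailing punctuation always stripped
  tok <- sub("[[:punct:]]+$", "", raw)
  lead <- substr(tok, 1L, 1L) %in% c("#", "@")
  # a leading # or @ stays attached; punctuation after it (or any leading
  # punctuation otherwise) is dropped
  tok[lead] <- paste0(substr(tok[lead], 1L, 1L),
                      sub("^[[:punct:]]+", "", substr(tok[lead], 2L, nchar(tok[lead]))))
  tok[!lead] <- sub("^[[:punct:]]+", "", tok[!lead])
  tok[nzchar(tok) & !(tok %in% c("#", "@"))]
}
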