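#' @name phone-inventory
#' @title ARPABET-style phone inventory helpers
#'
#' @description
#' Phone labels are interpreted against an ARPABET-style inventory: vowels
#' carry an optional trailing stress digit (1 = primary, 0/2 = non-primary),
#' stops are \code{P,T,K} (voiceless) and \code{B,D,G} (voiced). Matching is
#' case-insensitive.
#'
#' @param label character vector of phone labels.
#' @keywords internal
NULL

.SV_VOWELS <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                "IH", "IY", "OW", "OY", "UH", "UW")
.SV_STOPS_VOICELESS <- c("P", "T", "K")
.SV_STOPS_VOICED <- c("B", "D", "G")

# strip a trailing stress digit, uppercase
phone_base <- function(label) {
  toupper(sub("[0-2]$", "", label))
}

is_vowel <- function(label) {
  phone_base(label) %in% .SV_VOWELS
}

is_stop <- function(label, voicing = c("any", "voiceless", "voiced")) {
  voicing <- match.arg(voicing)
  base <- phone_base(label)
  switch(voicing,
         any = base %in% c(.SV_STOPS_VOICELESS, .SV_STOPS_VOICED),
         voiceless = base %in% .SV_STOPS_VOICELESS,
         voiced = base %in% .SV_STOPS_VOICED)
}

# stress from a label's trailing digit: "1" -> primary, "0"/"2" -> nonprimary,
# anything else -> none
label_stress <- function(label) {
  digit <- sub("^.*?([0-2])$", "\\1", label)
  out <- rep("none", length(label))
  out[digit == "1"] <- "primary"
  out[digit %in% c("0", "2")] <- "nonprimary"
  out[!grepl("[0-2]$", label)] <- "none"
  out
}
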