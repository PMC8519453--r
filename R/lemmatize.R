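# Rule-based English lemmatizer: an irregular-form table plus conservative
# suffix rules. Intentionally small: it canonicalizes the inflection patterns
# that matter for matching biomedical dictionary terms (plurals, -ed/-ing
# verb forms, be/have forms). Tokens containing digits or underscores are
# left untouched so gene symbols like "brca1" and joined concepts survive.

.irregular_lemmas <- c(
  am = "be", is = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", mice = "mouse", men = "man", women = "woman",
  children = "child", feet = "foot", teeth = "tooth", geese = "goose",
  people = "person", analyses = "analysis", hypotheses = "hypothesis",
  diagnoses = "diagnosis", bacteria = "bacterium", fungi = "fungus",
  nuclei = "nucleus", stimuli = "stimulus", criteria = "criterion",
  phenomena = "phenomenon", foci = "focus", loci = "locus",
  carcinomata = "carcinoma", went = "go", gone = "go", found = "find",
  showed = "show", shown = "show", gave = "give", given = "give",
  took = "take", taken = "take", made = "make", grew = "grow", grown = "grow"
)

# "y" counts as a vowel for the silent-e restoration check (analyzed -> analyze)
.vowel <- function(ch) ch %in% c("a", "e", "i", "o", "u", "y")

lemmatize_token <- function(tok) {
  if (grepl("[0-9_]", tok)) return(tok)
  irr <- .irregular_lemmas[tok]
  if (!is.na(irr)) return(unname(irr))
  if (nchar(tok) < 3L) return(tok)
  n <- nchar(tok)
  # plural / 3rd-person endings
  if (endsWith(tok, "ies") && n > 4L) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (endsWith(tok, "sses")) return(substr(tok, 1L, n - 2L))
  if (endsWith(tok, "xes") || endsWith(tok, "ches") || endsWith(tok, "shes"))
    return(substr(tok, 1L, n - 2L))
  if (endsWith(tok, "ied") && n > 4L) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (endsWith(tok, "ing") && n > 5L) {
    stem <- substr(tok, 1L, n - 3L)
    m <- nchar(stem)
    if (m >= 3L && substr(stem, m, m) == substr(stem, m - 1L, m - 1L) &&
        !.vowel(substr(stem, m, m)))
      stem <- substr(stem, 1L, m - 1L)  # running -> run
    return(stem)
  }
  if (endsWith(tok, "ed") && n > 4L) {
    stem <- substr(tok, 1L, n - 2L)
    m <- nchar(stem)
    if (m >= 3L && substr(stem, m, m) == substr(stem, m - 1L, m - 1L) &&
        !.vowel(substr(stem, m, m))) {
      stem <- substr(stem, 1L, m - 1L)  # stopped -> stop
    } else if (m >= 3L && !.vowel(substr(stem, m, m)) &&
               .vowel(substr(stem, m - 1L, m - 1L)) &&
               !.vowel(substr(stem, m - 2L, m - 2L))) {
      stem <- paste0(stem, "e")  # analyzed -> analyze
    }
    return(stem)
  }
  if (endsWith(tok, "s") && !endsWith(tok, "ss") && !endsWith(tok, "us") &&
      !endsWith(tok, "is") && n > 3L)
    return(substr(tok, 1L, n - 1L))
  tok
}

lemmatize_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(tokens)
  vapply(tokens, lemmatize_token, character(1L), USE.NAMES = FALSE)
}
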