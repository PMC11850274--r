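# Category lexicons (LIWC-style topic lexicon, affect lexicon), per-user
# word-proportion profiles, group comparisons and the six correlation word
# sets with their mean-embedding representations.

#' Construct a lexicon
#'
#' A lexicon is a named set of word categories. The topic lexicon used in
#' the analyses has 11 categories (social, family, friend, health, work,
#' leisure, money, religion, death, psychology, love); the emotion lexicon
#' has 7 (happy, like, surprise, angry, sad, fear, hate).
#'
#' @param categories Named list of character vectors (words per category).
#' @param name Lexicon name.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(categories, name = "lexicon") {
  if (length(categories) == 0) stopf("lexicon '%s' has no categories", name)
  if (is.null(names(categories)) || anyDuplicated(names(categories)))
    stopf("lexicon categories must have unique names")
  categories <- lapply(categories, function(w) unique(as.character(w)))
  empty <- names(categories)[vapply(categories, length, 1L) == 0]
  if (length(empty) > 0)
    stopf("empty categor%s: %s", if (length(empty) > 1) "ies" else "y",
          paste(empty, collapse = ", "))
  structure(list(name = name, categories = categories), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  sizes <- vapply(x$categories, length, 1L)
  cat(sprintf("<lexicon '%s': %d categories, %d words>\n", x$name,
              length(sizes), sum(sizes)))
  invisible(x)
}

#' Read a lexicon from TSV or JSON
#'
#' TSV rows are `category<TAB>word` (UTF-8, no header); JSON is an object
#' mapping category names to word arrays. Duplicate words within a category
#' are dropped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @param name Lexicon name; defaults to the file stem.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, format = c("auto", "tsv", "json"), name = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv", txt = "tsv",
                     stopf("cannot infer lexicon format from extension '%s'", ext))
  }
  name <- name %||% tools::file_path_sans_ext(basename(path))
  if (format == "tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stopf("lexicon file '%s' is empty", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2)
    if (length(bad) > 0) stopf("malformed TSV line %d in '%s'", bad[1], path)
    cats <- vapply(parts, `[[`, "", 1L)
    words <- vapply(parts, `[[`, "", 2L)
    lexicon(split(words, factor(cats, levels = unique(cats))), name = name)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(obj) == 0) stopf("lexicon file '%s' is empty", path)
    lexicon(as.list(obj), name = name)
  }
}

#' Write a lexicon as TSV
#' @param lex A [lexicon()].
#' @param path Output path.
#' @export
write_lexicon_tsv <- function(lex, path) {
  lines <- unlist(lapply(names(lex$categories), function(cat) {
    paste(cat, lex$categories[[cat]], sep = "\t")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Whitespace tokenizer
#' @param text Character vector.
#' @return List of token vectors, one per element of `text`.
#' @export
tokenize_whitespace <- function(text) {
  strsplit(trimws(text), "\\s+")
}

#' Character-unigram tokenizer
#'
#' Splits each text into single characters (whitespace dropped); a crude but
#' dependency-free option for unsegmented Chinese text.
#' @inheritParams tokenize_whitespace
#' @return List of token vectors.
#' @export
tokenize_chars <- function(text) {
  lapply(strsplit(gsub("\\s+", "", text), ""), function(x) x[nzchar(x)])
}

#' Per-category word proportions for a set of posts
#'
#' For each category, the proportion is `100 * matched / total` where
#' `matched` counts tokens that are members of the category and `total` is
#' the token count over all posts. Categories are scored independently: a
#' token belonging to several categories counts once in each. By default all
#' of a user's posts are pooled into one token stream; `per_post = TRUE`
#' instead averages per-post proportions.
#'
#' @param posts Character vector of post texts.
#' @param lex A [lexicon()].
#' @param tokenizer Function mapping a character vector to a list of token
#'   vectors; see [tokenize_whitespace()].
#' @param per_post Average per-post proportions instead of pooling tokens.
#' @return Named numeric vector of percentages, one per category.
#' @export
category_proportions <- function(posts, lex, tokenizer = tokenize_whitespace,
                                 per_post = FALSE) {
  toks <- tokenizer(posts)
  if (per_post) {
    lens <- vapply(toks, length, 1L)
    if (all(lens == 0)) stopf("no tokens in any post")
    keep <- lens > 0
    mat <- vapply(lex$categories, function(words) {
      vapply(toks[keep], function(tk) 100 * sum(tk %in% words) / length(tk), 0)
    }, numeric(sum(keep)))
    if (sum(keep) == 1) mat <- matrix(mat, nrow = 1,
                                      dimnames = list(NULL, names(lex$categories)))
    return(colMeans(mat))
  }
  all_tokens <- unlist(toks, use.names = FALSE)
  if (length(all_tokens) == 0) stopf("no tokens in any post")
  vapply(lex$categories, function(words) {
    100 * sum(all_tokens %in% words) / length(all_tokens)
  }, 0)
}

#' Per-user proportion profiles
#'
#' @param posts Data frame with columns `user_id` and `text`.
#' @param lex A [lexicon()].
#' @inheritParams category_proportions
#' @return Tibble with `user_id` and one percentage column per category.
#' @export
user_profiles <- function(posts, lex, tokenizer = tokenize_whitespace,
                          per_post = FALSE) {
  ids <- unique(posts$user_id)
  rows <- t(vapply(ids, function(uid) {
    category_proportions(posts$text[posts$user_id == uid], lex,
                         tokenizer = tokenizer, per_post = per_post)
  }, numeric(length(lex$categories))))
  out <- as_tibble(as.data.frame(rows))
  names(out) <- names(lex$categories)
  dplyr::bind_cols(tibble::tibble(user_id = ids), out)
}

#' Two-sample comparison of per-user proportions
#'
#' Student's two-sample t-test with pooled variance by default (`var_equal =
#' FALSE` switches to the Welch variant). When both groups are constant with
#' equal means the degenerate result `t = 0, p = 1` is returned; constant
#' groups with different means return `t = +/-Inf, p = 0`.
#'
#' @param a,b Numeric vectors of per-user values (each of length >= 2).
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @param alpha Significance thresholds, largest first.
#' @return One-row tibble: `mean_a`, `mean_b`, `diff` (a - b), `t`, `p`,
#'   `signif` (`"NS"`, `"*"`, `"**"`, `"***"`).
#' @export
compare_groups <- function(a, b, var_equal = TRUE,
                           alpha = c(0.05, 0.01, 0.001)) {
  if (length(a) < 2 || length(b) < 2)
    stopf("each group needs at least 2 observations")
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p_val <- if (d == 0) 1 else 0
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  stars <- c("*", "**", "***")
  level <- sum(p_val < sort(alpha, decreasing = TRUE))
  tibble::tibble(mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
                 t = t_stat, p = p_val,
                 signif = if (level == 0) "NS" else stars[level])
}

#' Group-level proportion tables
#'
#' Produces the analysis tables for a profiled corpus: per-group (and
#' optionally per-gender) mean proportions per category, a flag on the
#' per-category maximum, and a significance test of the maximum group
#' against the runner-up. With `gender` supplied, male-minus-female
#' differences within each group are tested as well.
#'
#' @param profiles Tibble from [user_profiles()] (`user_id` + category
#'   columns).
#' @param group Vector of group labels (e.g. style types), one per profile
#'   row.
#' @param gender Optional vector of gender labels, one per profile row.
#' @param var_equal Passed to [compare_groups()].
#' @return List with tibbles `means` (group x category means, with `n`),
#'   `max_tests` (per category: top group, runner-up, t, p, signif) and,
#'   when `gender` is given, `gender_means` and `gender_tests`.
#' @export
group_tables <- function(profiles, group, gender = NULL, var_equal = TRUE) {
  categories <- setdiff(names(profiles), "user_id")
  group <- as.character(group)
  tab <- table(group)
  empty <- names(tab)[tab == 0]
  if (length(empty) > 0) warning("omitting empty group(s): ",
                                 paste(empty, collapse = ", "))
  groups <- names(tab)[tab > 0]
  if (length(groups) < 2) stopf("need at least 2 non-empty groups")

  means <- dplyr::bind_rows(lapply(groups, function(g) {
    rows <- profiles[group == g, categories, drop = FALSE]
    dplyr::bind_cols(tibble::tibble(group = g, n = nrow(rows)),
                     as_tibble(as.list(colMeans(rows))))
  }))

  max_tests <- dplyr::bind_rows(lapply(categories, function(cat) {
    m <- means[[cat]]
    ord <- order(m, decreasing = TRUE)
    top <- groups[ord[1]]; second <- groups[ord[2]]
    a <- profiles[[cat]][group == top]
    b <- profiles[[cat]][group == second]
    cmp <- if (length(a) >= 2 && length(b) >= 2)
      compare_groups(a, b, var_equal = var_equal)
    else tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                        diff = mean(a) - mean(b), t = NA_real_, p = NA_real_,
                        signif = NA_character_)
    tibble::tibble(category = cat, top_group = top, runner_up = second,
                   diff = cmp$diff, t = cmp$t, p = cmp$p, signif = cmp$signif)
  }))

  out <- list(means = means, max_tests = max_tests)

  if (!is.null(gender)) {
    gender <- as.character(gender)
    combos <- expand.grid(group = groups, gender = sort(unique(gender)),
                          stringsAsFactors = FALSE)
    out$gender_means <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
      sel <- group == combos$group[i] & gender == combos$gender[i]
      if (!any(sel)) return(NULL)
      dplyr::bind_cols(tibble::tibble(group = combos$group[i],
                                      gender = combos$gender[i], n = sum(sel)),
                       as_tibble(as.list(colMeans(profiles[sel, categories,
                                                           drop = FALSE]))))
    }))
    out$gender_tests <- dplyr::bind_rows(lapply(groups, function(g) {
      dplyr::bind_rows(lapply(categories, function(cat) {
        a <- profiles[[cat]][group == g & gender == "male"]
        b <- profiles[[cat]][group == g & gender == "female"]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        cmp <- compare_groups(a, b, var_equal = var_equal)
        tibble::tibble(group = g, category = cat, male_minus_female = cmp$diff,
                       t = cmp$t, p = cmp$p, signif = cmp$signif)
      }))
    }))
  }
  out
}

#' Default mapping of lexicon categories to the six correlation word sets
#'
#' Topic sets: `T_p` (social, family, friend, work, leisure, money,
#' psychology), `T_m` (religion), `T_n` (health, death, love). Emotion sets:
#' `E_p` (happy, angry), `E_m` (like, surprise), `E_n` (sad, fear, hate).
#' Note the published set composition places "angry" with the positive-style
#' emotion set even though it is a negative emotion category; the default
#' follows that composition verbatim.
#'
#' @return Named list mapping set names to category names.
#' @export
default_word_set_mapping <- function() {
  list(
    T_p = c("social", "family", "friend", "work", "leisure", "money", "psychology"),
    E_p = c("happy", "angry"),
    T_m = "religion",
    E_m = c("like", "surprise"),
    T_n = c("health", "death", "love"),
    E_n = c("sad", "fear", "hate")
  )
}

#' Build the six correlation word sets
#'
#' Each set is the union of its mapped categories' words, drawn from the
#' topic and emotion lexicons.
#'
#' @param topic_lex,emotion_lex [lexicon()] objects.
#' @param mapping Named list mapping each set name to category names; see
#'   [default_word_set_mapping()].
#' @return An object of class `word_set_bundle` with elements `sets` (named
#'   list of word vectors, in the order of `mapping`) and `sizes`.
#' @export
build_word_sets <- function(topic_lex, emotion_lex,
                            mapping = default_word_set_mapping()) {
  all_cats <- c(topic_lex$categories, emotion_lex$categories)
  sets <- lapply(mapping, function(cats) {
    missing <- setdiff(cats, names(all_cats))
    if (length(missing) > 0)
      stopf("mapped categor%s not found in lexicons: %s",
            if (length(missing) > 1) "ies" else "y",
            paste(missing, collapse = ", "))
    unique(unlist(all_cats[cats], use.names = FALSE))
  })
  structure(list(sets = sets, sizes = vapply(sets, length, 1L)),
            class = "word_set_bundle")
}

#' @export
print.word_set_bundle <- function(x, ...) {
  cat("<word_set_bundle>\n")
  for (nm in names(x$sets)) {
    extra <- if (!is.null(x$representations))
      sprintf("  (representation width %d)", length(x$representations[[nm]])) else ""
    cat(sprintf("  %-4s %6d words%s\n", nm, x$sizes[[nm]], extra))
  }
  invisible(x)
}

#' Mean-embedding representation of a word set
#'
#' @param words Non-empty character vector.
#' @param embedder Function mapping a character vector of words to a
#'   numeric matrix (one row per word); see [word_embedder()].
#' @return Numeric vector: the arithmetic mean of the word embeddings.
#' @export
set_representation <- function(words, embedder) {
  if (length(words) == 0) stopf("cannot represent an empty word set")
  colMeans(embedder(words))
}

#' Attach mean-embedding representations to a word-set bundle
#'
#' Computes [set_representation()] for each of the six sets and stores them
#' (plus their concatenation in the bundle's set order, which is the order
#' the assessment model's injection layer uses).
#'
#' @param bundle A [build_word_sets()] result.
#' @param embedder Word-embedding function, see [word_embedder()].
#' @return The bundle with `representations` (named list) and `rep_vector`.
#' @export
bundle_representations <- function(bundle, embedder) {
  bundle$representations <- lapply(bundle$sets, set_representation,
                                   embedder = embedder)
  widths <- vapply(bundle$representations, length, 1L)
  if (length(unique(widths)) != 1)
    stopf("embedder returned inconsistent widths: %s", paste(widths, collapse = ","))
  bundle$rep_vector <- unlist(bundle$representations, use.names = FALSE)
  bundle
}
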