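#' Patient-record diagnosis datasets
#'
#' A `diag_dataset` holds an ordered collection of patient records together
#' with the symptom and disease vocabularies they are expressed in.  Each
#' record carries a disease label, the disease's group (department), the
#' symptoms the patient volunteers at the start of a dialogue (explicit
#' symptoms, the self-report) and the symptoms only discoverable by querying
#' (implicit symptoms), each with a true/false status.
#'
#' Vocabulary orderings are stable and are part of the on-disk format:
#' index positions of symptoms define the layout of every state encoding
#' downstream.
#'
#' @param records list of patient records; each record is a list with
#'   elements `record_id` (unique string), `disease` (string),
#'   `explicit` and `implicit` (named logical vectors keyed by symptom,
#'   disjoint, with at least one explicit entry).
#' @param symptoms character vector, the ordered symptom vocabulary.
#' @param diseases character vector, the ordered disease vocabulary.
#' @param group_map named character vector mapping every disease to its
#'   disease-group (department) identifier.
#' @return An object of class `diag_dataset`: a list with elements
#'   `symptoms`, `diseases`, `group_map`, `groups` (ordered unique groups)
#'   and `records`.
#' @examples
#' d <- diag_dataset(
#'   records = list(list(record_id = "r1", disease = "flu",
#'                       explicit = c(cough = TRUE),
#'                       implicit = c(fever = TRUE))),
#'   symptoms = c("cough", "fever"),
#'   diseases = "flu",
#'   group_map = c(flu = "respiratory"))
#' dataset_statistics(d)
#' @export
diag_dataset <- function(records, symptoms, diseases, group_map) {
  stopifnot(is.character(symptoms), is.character(diseases),
            is.character(group_map), is.list(records))
  if (anyDuplicated(symptoms)) stop("duplicate symptom identifiers")
  if (anyDuplicated(diseases)) stop("duplicate disease identifiers")
  if (!setequal(names(group_map), diseases) ||
      length(group_map) != length(diseases))
    stop("group_map must assign exactly one group to every disease")
  group_map <- group_map[diseases]
  x <- structure(list(symptoms = symptoms,
                      diseases = diseases,
                      group_map = group_map,
                      groups = unique(unname(group_map)),
                      records = records),
                 class = "diag_dataset")
  validate_dataset(x)
  x
}

validate_dataset <- function(x) {
  ids <- vapply(x$records, function(r) as.character(r$record_id), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id: ", dup[[1L]])
  for (r in x$records) {
    where <- paste0("record '", r$record_id, "'")
    if (!is.character(r$disease) || !(r$disease %in% x$diseases))
      stop(where, ": unknown disease '", r$disease, "'")
    ex <- r$explicit; im <- r$implicit
    if (length(ex) == 0L)
      stop(where, ": needs at least one explicit symptom")
    if (!all(names(ex) %in% x$symptoms))
      stop(where, ": unknown symptom '",
           setdiff(names(ex), x$symptoms)[[1L]], "'")
    if (!all(names(im) %in% x$symptoms))
      stop(where, ": unknown symptom '",
           setdiff(names(im), x$symptoms)[[1L]], "'")
    if (length(intersect(names(ex), names(im))))
      stop(where, ": explicit and implicit symptom sets overlap")
    if (!is.logical(ex) || (length(im) && !is.logical(im)))
      stop(where, ": symptom statuses must be logical")
  }
  invisible(x)
}

#' @export
print.diag_dataset <- function(x, ...) {
  cat(sprintf(paste0("<diag_dataset> %d records, %d diseases in %d groups, ",
                     "%d symptoms\n"),
              length(x$records), length(x$diseases), length(x$groups),
              length(x$symptoms)))
  invisible(x)
}

#' @export
summary.diag_dataset <- function(object, ...) dataset_statistics(object)

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the structure of a large multi-department diagnosis
#' corpus: 9 disease groups of 10 diseases each over a 266-symptom
#' vocabulary, one self-reported symptom and on average 2.6 implicit
#' symptoms per record.
#'
#' @param n_groups number of disease groups (departments).
#' @param diseases_per_group diseases per group.
#' @param n_symptoms size of the symptom vocabulary.
#' @param group_symptom_overlap fraction of the vocabulary set aside as
#'   "common" symptoms shared across all groups; the remainder is split
#'   evenly into group-specific pools.  Shared symptoms are the source of
#'   cross-group diagnostic confusion.
#' @param mean_explicit expected number of explicit (self-report) symptoms
#'   per record; at least one is always present.
#' @param mean_implicit expected number of implicit symptoms per record.
#' @param disease_symptom_profile_size number of symptoms in each disease's
#'   fixed symptom profile.
#' @param negative_implicit_rate fraction of implicit entries recorded with
#'   status `FALSE` (negated findings).
#' @param n_records number of records to generate.
#' @param seed integer seed making generation deterministic.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_groups = 9L,
                             diseases_per_group = 10L,
                             n_symptoms = 266L,
                             group_symptom_overlap = 0.15,
                             mean_explicit = 1,
                             mean_implicit = 2.6,
                             disease_symptom_profile_size = 12L,
                             negative_implicit_rate = 0,
                             n_records = 30000L,
                             seed = 42L) {
  cfg <- list(n_groups = as.integer(n_groups),
              diseases_per_group = as.integer(diseases_per_group),
              n_symptoms = as.integer(n_symptoms),
              group_symptom_overlap = group_symptom_overlap,
              mean_explicit = mean_explicit,
              mean_implicit = mean_implicit,
              disease_symptom_profile_size =
                as.integer(disease_symptom_profile_size),
              negative_implicit_rate = negative_implicit_rate,
              n_records = as.integer(n_records),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_groups >= 1L, diseases_per_group >= 1L, n_symptoms >= 1L,
              n_records >= 0L, disease_symptom_profile_size >= 1L,
              mean_explicit >= 1, mean_implicit >= 0)
    if (group_symptom_overlap < 0 || group_symptom_overlap > 1 ||
        negative_implicit_rate < 0 || negative_implicit_rate > 1)
      stop("fractions must lie in [0, 1]")
  })
  if (cfg$disease_symptom_profile_size <
      cfg$mean_explicit + cfg$mean_implicit)
    stop("disease_symptom_profile_size smaller than mean_explicit + ",
         "mean_implicit: profiles cannot host an average record")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic diagnosis dataset
#'
#' Builds a corpus of simulated patient records.  The symptom vocabulary is
#' split into a shared "common" pool and per-group pools; each disease draws
#' a fixed symptom profile from its group pool plus the commons; each record
#' then samples its explicit and implicit symptoms from its disease's
#' profile.  Explicit counts are `1 + Poisson(mean_explicit - 1)` and
#' implicit counts `Poisson(mean_implicit)` (truncated so a record never
#' exceeds its profile), so sample means converge to the configured means.
#' Record labels are balanced across diseases.
#'
#' @param config a [generator_config()].
#' @return A [diag_dataset()].  Deterministic given `config$seed`.
#' @export
generate_synthetic_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_sym <- config$n_symptoms
  symptoms <- sprintf("symptom_%03d", seq_len(n_sym))
  n_shared <- round(config$group_symptom_overlap * n_sym)
  shared <- if (n_shared > 0L) sample(symptoms, n_shared) else character(0)
  specific <- setdiff(symptoms, shared)
  # deal group-specific pools round-robin from a shuffled deck
  pools <- split(sample(specific),
                 rep_len(seq_len(config$n_groups), length(specific)))

  groups <- sprintf("group_%d", seq_len(config$n_groups))
  diseases <- character(0)
  group_map <- character(0)
  profiles <- list()
  psize <- config$disease_symptom_profile_size
  for (g in seq_len(config$n_groups)) {
    pool <- c(pools[[g]], shared)
    if (length(pool) < psize)
      stop("group pool smaller than disease_symptom_profile_size")
    for (d in seq_len(config$diseases_per_group)) {
      id <- sprintf("disease_g%d_%02d", g, d)
      diseases <- c(diseases, id)
      group_map[id] <- groups[g]
      profiles[[id]] <- sample(pool, psize)
    }
  }

  records <- vector("list", config$n_records)
  nd <- length(diseases)
  for (i in seq_len(config$n_records)) {
    dis <- diseases[[(i - 1L) %% nd + 1L]]
    prof <- profiles[[dis]]
    n_ex <- min(1L + stats::rpois(1L, config$mean_explicit - 1),
                length(prof))
    n_im <- min(stats::rpois(1L, config$mean_implicit),
                length(prof) - n_ex)
    picked <- sample(prof, n_ex + n_im)
    ex <- stats::setNames(rep(TRUE, n_ex), picked[seq_len(n_ex)])
    im_names <- picked[seq_len(n_im) + n_ex]
    im <- stats::setNames(
      stats::runif(n_im) >= config$negative_implicit_rate, im_names)
    records[[i]] <- list(record_id = sprintf("case_%05d", i),
                         disease = dis,
                         explicit = ex,
                         implicit = im)
  }
  diag_dataset(records, symptoms, diseases, group_map)
}

# preserve caller RNG state around seeded sections
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Summary statistics of a diagnosis dataset
#'
#' Reports corpus-level counts: diseases, groups, symptoms, mean explicit
#' and implicit symptoms per record, and per-group record totals.
#'
#' @param dataset a [diag_dataset()].
#' @return A list of class `diag_dataset_stats` with elements `n_records`,
#'   `n_diseases`, `n_groups`, `n_symptoms`, `mean_explicit`,
#'   `mean_implicit` (the last two `NA` on an empty dataset) and
#'   `records_per_group` (named integer vector).
#' @export
dataset_statistics <- function(dataset) {
  stopifnot(inherits(dataset, "diag_dataset"))
  n <- length(dataset$records)
  nex <- vapply(dataset$records, function(r) length(r$explicit), 0L)
  nim <- vapply(dataset$records, function(r) length(r$implicit), 0L)
  rec_groups <- vapply(dataset$records,
                       function(r) unname(dataset$group_map[[r$disease]]), "")
  per_group <- stats::setNames(integer(length(dataset$groups)),
                               dataset$groups)
  if (n > 0L) {
    tab <- table(factor(rec_groups, levels = dataset$groups))
    per_group[] <- as.integer(tab)
  }
  structure(list(n_records = n,
                 n_diseases = length(dataset$diseases),
                 n_groups = length(dataset$groups),
                 n_symptoms = length(dataset$symptoms),
                 mean_explicit = if (n) mean(nex) else NA_real_,
                 mean_implicit = if (n) mean(nim) else NA_real_,
                 records_per_group = per_group),
            class = "diag_dataset_stats")
}

#' @export
print.diag_dataset_stats <- function(x, ...) {
  cat("Diagnosis dataset statistics\n")
  cat(sprintf("  records:        %d\n", x$n_records))
  cat(sprintf("  diseases:       %d in %d groups\n", x$n_diseases,
              x$n_groups))
  cat(sprintf("  symptoms:       %d\n", x$n_symptoms))
  cat(sprintf("  mean explicit:  %s\n", format(x$mean_explicit, digits = 4)))
  cat(sprintf("  mean implicit:  %s\n", format(x$mean_implicit, digits = 4)))
  invisible(x)
}

#' Split a dataset into train and test partitions
#'
#' Deterministically shuffles the records and partitions them; both halves
#' keep the full vocabularies so index layouts are unchanged.
#'
#' @param dataset a [diag_dataset()].
#' @param train_fraction proportion of records in the training half,
#'   strictly between 0 and 1.
#' @param seed integer seed for the shuffle.
#' @return A list with elements `train` and `test`, both `diag_dataset`s,
#'   disjoint and jointly covering all records.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "diag_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- length(dataset$records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_train <- round(train_fraction * n)
  mk <- function(i) diag_dataset(dataset$records[sort(i)], dataset$symptoms,
                                 dataset$diseases, dataset$group_map)
  list(train = mk(idx[seq_len(n_train)]),
       test = mk(idx[setdiff(seq_len(n), seq_len(n_train))]))
}

## ---- on-disk format --------------------------------------------------------

record_to_json_list <- function(r) {
  as_map <- function(v) {
    v <- v[order(names(v))]
    stats::setNames(as.list(unname(v)), names(v))
  }
  list(disease = r$disease,
       explicit = as_map(r$explicit),
       implicit = as_map(r$implicit),
       record_id = as.character(r$record_id))
}

#' Write a dataset to its canonical JSON form
#'
#' The format is UTF-8 JSON with top-level keys `"diseases"` (ordered list
#' of `{group, id}`), `"records"` and `"symptoms"` (the ordered
#' vocabulary).  Keys are sorted within every object so serialization is
#' canonical: writing, reading and writing again produces identical bytes.
#'
#' @param dataset a [diag_dataset()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "diag_dataset"))
  obj <- list(
    diseases = lapply(dataset$diseases, function(d)
      list(group = unname(dataset$group_map[[d]]), id = d)),
    records = lapply(dataset$records, record_to_json_list),
    symptoms = as.list(dataset$symptoms))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a dataset from its JSON form
#'
#' @param path file written by [write_dataset()] (or conforming to the same
#'   format).
#' @return A validated [diag_dataset()]; errors name the offending record.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed dataset JSON: ", conditionMessage(e)))
  for (key in c("symptoms", "diseases", "records"))
    if (is.null(obj[[key]])) stop("dataset JSON missing key '", key, "'")
  symptoms <- vapply(obj$symptoms, as.character, "")
  diseases <- vapply(obj$diseases, function(d) as.character(d$id), "")
  group_map <- stats::setNames(
    vapply(obj$diseases, function(d) as.character(d$group), ""), diseases)
  as_status <- function(m) {
    v <- vapply(m, function(x) isTRUE(x), NA)
    stats::setNames(v, names(m))
  }
  records <- lapply(obj$records, function(r)
    list(record_id = as.character(r$record_id),
         disease = as.character(r$disease),
         explicit = as_status(r$explicit),
         implicit = as_status(r$implicit)))
  diag_dataset(records, symptoms, diseases, group_map)
}

datasets_equal <- function(a, b) {
  identical(a$symptoms, b$symptoms) && identical(a$diseases, b$diseases) &&
    identical(a$group_map, b$group_map) &&
    length(a$records) == length(b$records) &&
    all(vapply(seq_along(a$records), function(i) {
      x <- a$records[[i]]; y <- b$records[[i]]
      identical(x$record_id, y$record_id) &&
        identical(x$disease, y$disease) &&
        identical(x$explicit[order(names(x$explicit))],
                  y$explicit[order(names(y$explicit))]) &&
        identical(x$implicit[order(names(x$implicit))],
                  y$implicit[order(names(y$implicit))])
    }, NA))
}
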