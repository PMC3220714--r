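#' Robust-design capture-history dataset
#'
#' Container for individual binary encounter histories under a robust
#' design. Each individual carries a T x K encounter matrix (primary
#' sessions by secondary occasions) and, for every capture, an age class
#' (`"young"` or `"adult"`; adults are animals with the third upper molar
#' erupted). Age classes may never revert from adult to young.
#'
#' @param design An [rd_design()].
#' @param individuals A list; each element is a list with fields `id`,
#'   `patch_id`, `enc` (T x K 0/1 matrix with at least one 1) and `age`
#'   (T x K character matrix, `"young"`/`"adult"` exactly where `enc == 1`,
#'   `NA` elsewhere). If `age` is omitted all captures are taken as adult.
#'
#' @return An object of class `rd_data`.
#' @export
rd_data <- function(design, individuals) {
  stopifnot(inherits(design, "rd_design"))
  T_ <- design$n_primary; K <- design$n_secondary
  ids <- vapply(individuals, function(x) as.character(x$id), character(1))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  individuals <- lapply(individuals, function(x) {
    x$id <- as.character(x$id)
    x$patch_id <- as.character(x$patch_id)
    if (!x$patch_id %in% design$patches$patch_id)
      stop("unknown patch id: ", x$patch_id)
    enc <- as.matrix(x$enc)
    if (!all(dim(enc) == c(T_, K)))
      stop("encounter matrix of ", x$id, " is not ", T_, " x ", K)
    if (!all(enc %in% c(0L, 1L)))
      stop("encounter matrix of ", x$id, " must be binary")
    storage.mode(enc) <- "integer"
    if (sum(enc) == 0L)
      stop("individual ", x$id, " has an all-zero encounter matrix")
    if (is.null(x$age)) {
      age <- matrix(NA_character_, T_, K)
      age[enc == 1L] <- "adult"
    } else {
      age <- matrix(as.character(x$age), T_, K)
    }
    if (!all(is.na(age[enc == 0L])))
      stop("individual ", x$id, ": age defined where there is no capture")
    if (anyNA(age[enc == 1L]) ||
        !all(age[enc == 1L] %in% c("young", "adult")))
      stop("individual ", x$id,
           ": every capture needs an age class 'young' or 'adult'")
    young_s <- which(apply(age == "young" & enc == 1L, 1, any, na.rm = TRUE))
    adult_s <- which(apply(age == "adult" & enc == 1L, 1, any, na.rm = TRUE))
    if (length(young_s) && length(adult_s) &&
        max(young_s) >= min(adult_s))
      stop("individual ", x$id, ": age may not revert from adult to young")
    x$enc <- enc; x$age <- age
    x[c("id", "patch_id", "enc", "age")]
  })
  names(individuals) <- ids
  structure(list(design = design, individuals = individuals),
            class = "rd_data")
}

#' @export
print.rd_data <- function(x, ...) {
  cat("Robust-design dataset:", length(x$individuals), "individuals,",
      x$design$n_primary, "x", x$design$n_secondary, "occasions,",
      nrow(x$design$patches), "patches\n")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param data An [rd_data()] object.
#' @export
n_individuals <- function(data) length(data$individuals)

#' Collapse an encounter matrix to primary-session detections
#'
#' Reduces a T x K encounter matrix to the length-T binary vector consumed
#' by the open-population likelihood: detected in primary session t iff
#' captured on at least one of its secondary occasions.
#'
#' @param enc A T x K binary matrix with at least one 1.
#' @return A list with `detected` (integer vector of length T), `first`
#'   and `last` (indices of first and last detection, 1-based).
#' @export
collapse_history <- function(enc) {
  enc <- as.matrix(enc)
  if (!all(enc %in% c(0, 1))) stop("encounter matrix must be binary")
  if (sum(enc) == 0) stop("cannot collapse an all-zero encounter matrix")
  det <- as.integer(rowSums(enc) > 0)
  w <- which(det == 1L)
  list(detected = det, first = w[1L], last = w[length(w)])
}

#' Reduce a dataset to its adult encounters
#'
#' Removes every capture made while an individual was classified as young
#' (animals recruited in situ, hence not immigrants), and drops individuals
#' left without any capture. With `drop_ever_young = TRUE` the stricter rule
#' is applied: any individual ever caught as young is dropped entirely,
#' including its later adult captures.
#'
#' @param data An [rd_data()] object.
#' @param drop_ever_young Apply the stricter all-or-nothing rule.
#' @return An [rd_data()] with the same design.
#' @export
reduce_to_adults <- function(data, drop_ever_young = FALSE) {
  stopifnot(inherits(data, "rd_data"))
  kept <- list()
  for (ind in data$individuals) {
    any_young <- any(ind$age == "young", na.rm = TRUE)
    if (drop_ever_young && any_young) next
    enc <- ind$enc; age <- ind$age
    drop <- which(age == "young")
    enc[drop] <- 0L; age[drop] <- NA_character_
    if (sum(enc) == 0L) next
    kept[[length(kept) + 1L]] <-
      list(id = ind$id, patch_id = ind$patch_id, enc = enc, age = age)
  }
  rd_data(data$design, kept)
}

#' Distinct individuals captured per patch and primary session
#'
#' Returns the M(t+1) table: the number of distinct individuals captured at
#' least once in each primary session of each patch. These counts are the
#' hard lower bounds for the Huggins abundance estimates.
#'
#' @param data An [rd_data()] object.
#' @return An integer matrix, patches (rows, in design order) x sessions.
#' @export
mt1_per_session <- function(data) {
  stopifnot(inherits(data, "rd_data"))
  des <- data$design
  m <- matrix(0L, nrow(des$patches), des$n_primary,
              dimnames = list(des$patches$patch_id,
                              paste0("session", seq_len(des$n_primary))))
  for (ind in data$individuals) {
    det <- rowSums(ind$enc) > 0
    m[ind$patch_id, ] <- m[ind$patch_id, ] + as.integer(det)
  }
  m
}

## ---- long-format CSV I/O ------------------------------------------------

#' Convert a dataset to a long capture data frame
#'
#' One row per capture event, with 1-based session and occasion indices.
#'
#' @param data An [rd_data()] object.
#' @return Data frame with columns individual_id, patch_id, session,
#'   occasion, age.
#' @export
as_capture_df <- function(data) {
  stopifnot(inherits(data, "rd_data"))
  rows <- lapply(data$individuals, function(ind) {
    w <- which(ind$enc == 1L, arr.ind = TRUE)
    data.frame(individual_id = ind$id, patch_id = ind$patch_id,
               session = w[, 1L], occasion = w[, 2L],
               age = ind$age[w], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out))
    out <- data.frame(individual_id = character(), patch_id = character(),
                      session = integer(), occasion = integer(),
                      age = character())
  out[order(out$individual_id, out$session, out$occasion), , drop = FALSE]
}

#' Build a dataset from a long capture data frame
#'
#' @param design An [rd_design()].
#' @param df Data frame with columns individual_id, patch_id, session,
#'   occasion and optionally age (default adult).
#' @return An [rd_data()] object.
#' @export
rd_data_from_df <- function(design, df) {
  stopifnot(inherits(design, "rd_design"))
  df <- as.data.frame(df)
  need <- c("individual_id", "patch_id", "session", "occasion")
  if (!all(need %in% names(df)))
    stop("capture data frame needs columns ", paste(need, collapse = ", "))
  if (is.null(df$age)) df$age <- "adult"
  T_ <- design$n_primary; K <- design$n_secondary
  if (nrow(df) &&
      (any(df$session < 1 | df$session > T_) ||
       any(df$occasion < 1 | df$occasion > K)))
    stop("session/occasion indices outside the design")
  inds <- lapply(split(df, df$individual_id), function(d) {
    enc <- matrix(0L, T_, K)
    age <- matrix(NA_character_, T_, K)
    idx <- cbind(d$session, d$occasion)
    enc[idx] <- 1L
    age[idx] <- as.character(d$age)
    list(id = d$individual_id[1L], patch_id = d$patch_id[1L],
         enc = enc, age = age)
  })
  rd_data(design, unname(inds))
}

#' Read / write capture histories as CSV
#'
#' Long format with columns individual_id, patch_id, session, occasion, age.
#'
#' @param data An [rd_data()] object.
#' @param path File path.
#' @param design An [rd_design()] describing the file's layout.
#' @return `write_capture_csv` returns `path` invisibly; `read_capture_csv`
#'   returns an [rd_data()].
#' @export
write_capture_csv <- function(data, path) {
  utils::write.csv(as_capture_df(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capture_csv
#' @export
read_capture_csv <- function(path, design) {
  rd_data_from_df(design, utils::read.csv(path, stringsAsFactors = FALSE))
}

## ---- MARK .inp encounter-history I/O ------------------------------------

#' Write capture histories in MARK `.inp` encounter-history format
#'
#' Each line holds one individual: an optional leading `/* ... */` comment
#' carrying the individual id and an age string, the session-major encounter
#' string of length T*K over {0,1}, one frequency column per patch (1 for
#' the individual's patch, 0 elsewhere), and a terminating semicolon. The
#' age string has one character per position: `.` no capture, `Y` young
#' capture, `A` adult capture; it makes the round trip through `.inp`
#' lossless for this package's data model.
#'
#' @param data An [rd_data()] object.
#' @param path Output file path.
#' @param design An [rd_design()]; histories are validated against it.
#' @return `write_inp` returns `path` invisibly; `read_inp` an [rd_data()].
#' @export
write_inp <- function(data, path) {
  stopifnot(inherits(data, "rd_data"))
  des <- data$design
  pids <- des$patches$patch_id
  lines <- vapply(data$individuals, function(ind) {
    hist <- paste(as.integer(t(ind$enc)), collapse = "")
    agev <- as.character(t(ind$age))
    agev[is.na(agev)] <- "."
    agev[agev == "young"] <- "Y"
    agev[agev == "adult"] <- "A"
    freq <- as.integer(pids == ind$patch_id)
    paste0("/* id=", ind$id, " ages=", paste(agev, collapse = ""), " */ ",
           hist, " ", paste(freq, collapse = " "), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_inp
#' @export
read_inp <- function(path, design) {
  stopifnot(inherits(design, "rd_design"))
  T_ <- design$n_primary; K <- design$n_secondary
  len <- T_ * K
  pids <- design$patches$patch_id
  lines <- readLines(path)
  inds <- list()
  auto <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (!grepl(";\\s*$", line))
      stop("line ", i, ": missing terminating semicolon")
    line <- sub(";\\s*$", "", line)
    id <- NA_character_; ages_str <- NA_character_
    cm <- regmatches(line, gregexpr("/\\*.*?\\*/", line))[[1]]
    if (length(cm)) {
      body <- gsub("^/\\*|\\*/$", "", cm[[1L]])
      m_id <- regmatches(body, regexec("id=(\\S+)", body))[[1]]
      if (length(m_id) == 2L) id <- m_id[[2L]]
      m_ag <- regmatches(body, regexec("ages=([.YA]+)", body))[[1]]
      if (length(m_ag) == 2L) ages_str <- m_ag[[2L]]
    }
    line <- gsub("/\\*.*?\\*/", " ", line)
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) < 1L + length(pids))
      stop("line ", i, ": expected an encounter string and ",
           length(pids), " frequency columns")
    hist <- toks[[1L]]
    if (nchar(hist) != len)
      stop("line ", i, ": encounter string has length ", nchar(hist),
           ", expected ", len)
    if (grepl("[^01]", hist))
      stop("line ", i, ": encounter string contains non-binary characters")
    freq <- suppressWarnings(as.integer(toks[-1L]))
    if (anyNA(freq) || length(freq) != length(pids))
      stop("line ", i, ": malformed frequency columns")
    grp <- which(freq > 0L)
    if (length(grp) != 1L)
      stop("line ", i, ": exactly one positive frequency column expected")
    enc <- matrix(as.integer(strsplit(hist, "")[[1]]), T_, K, byrow = TRUE)
    age <- matrix(NA_character_, T_, K)
    if (!is.na(ages_str)) {
      if (nchar(ages_str) != len)
        stop("line ", i, ": ages string has wrong length")
      av <- matrix(strsplit(ages_str, "")[[1]], T_, K, byrow = TRUE)
      age[av == "Y"] <- "young"; age[av == "A"] <- "adult"
    } else {
      age[enc == 1L] <- "adult"
    }
    for (rep in seq_len(freq[grp])) {
      auto <- auto + 1L
      this_id <- if (!is.na(id) && freq[grp] == 1L) id
                 else paste0(if (is.na(id)) "ind" else id, "_", auto)
      inds[[length(inds) + 1L]] <-
        list(id = this_id, patch_id = pids[grp], enc = enc, age = age)
    }
  }
  rd_data(design, inds)
}
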