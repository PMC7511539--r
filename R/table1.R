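# Packaged participant fixtures. table1_participants.csv is a verbatim
# transcription of the study's descriptive table (25 participants: group,
# sex, age, competitiveness, extra familiarization trials, musical training,
# physical activity, and GXT / interval-test outcomes);
# table2_hiit_dose.csv records the completed high-intensity dose for the
# five participants who abandoned the interval protocol.

TABLE1_MD5 <- "5b8a583e9d6032b2b6f3ed985034e983"
TABLE2_MD5 <- "ed37fcb0f4d5bb9f15603db581434559"

#' Load the packaged participant table
#'
#' Returns the 25-participant descriptive table (one row per participant)
#' with group (`High` = HIIT, `Low` = LIIT), sex, age, competitiveness (1-7),
#' extra familiarization trials (`eft`), musical training in months
#' (`m_train`), physical activity (`ipaq`, MET-minutes/week), VO2peak
#' (ml/kg/min), W_max (watts), and the HR / RER / RPE maxima of the graded
#' exercise test (`gxt_*`) and interval exercise test (`iet_*`).
#'
#' The fixture is checksum-verified and structurally validated on load
#' (25 rows; 13 High / 12 Low; W_max on the sex-specific 30 W power grids).
#'
#' @return A tibble with 25 rows.
#' @examples
#' t1 <- load_table1()
#' mean(t1$age[t1$group == "Low"]) # 21.5
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_participants.csv",
                      package = "pianoskill")
  if (path == "") stop("packaged participant table not found", call. = FALSE)
  if (unname(tools::md5sum(path)) != TABLE1_MD5)
    stop("participant table fixture failed its checksum: file was modified",
         call. = FALSE)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(nrow(d) == 25L,
            sum(d$group == "High") == 13L,
            sum(d$group == "Low") == 12L,
            all(d$sex %in% c("M", "F")))
  grid <- c(build_gxt_schedule("M", 8)$power_w, build_gxt_schedule("F", 8)$power_w)
  stopifnot(all(d$wmax %in% grid))
  d
}

#' Load the packaged incomplete-protocol dose table
#'
#' High-intensity interval training doses actually completed by the five
#' participants who stopped the interval test early (volitional exhaustion).
#' Doses are returned both as printed labels and in seconds. Some doses
#' exceed the 9 minutes of the printed 3 x 3-min schedule; the table is
#' taken at face value (see [hiit_dose_completed()]).
#'
#' @return A tibble with columns `pt`, `dose` (label), `dose_s` (seconds).
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_hiit_dose.csv",
                      package = "pianoskill")
  if (path == "") stop("packaged dose table not found", call. = FALSE)
  if (unname(tools::md5sum(path)) != TABLE2_MD5)
    stop("dose table fixture failed its checksum: file was modified",
         call. = FALSE)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(d$pt %in% c(16L, 17L, 20L, 21L, 24L)))
  d$dose_s <- parse_dose_label(d$dose)
  d
}
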