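# Small in-code fixtures shared across test files.

DAY <- 86400

dt_at <- function(day, hour = 9) {
  as.POSIXct("2019-01-01 00:00", tz = "UTC") + day * DAY + hour * 3600
}

# minimal results table for hand-built cohorts
mk_results <- function(mpi, day, scr, lab = "L01",
                       dob = as.Date("1960-06-15"), sex = "F", hour = 9) {
  data.frame(mpi = mpi, lab_code = lab, specimen_dt = dt_at(day, hour),
             scr = scr, dob = dob, sex = sex)
}

mk_alerts <- function(mpi, day, stage, lab = "L01", hour = 9) {
  data.frame(mpi = mpi, lab_code = lab, alert_dt = dt_at(day, hour),
             stage = stage)
}

write_scr_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("mpi,lab_code,specimen_dt,scr_umol_l,dob,sex,location_code",
               lines), path)
  path
}

write_alert_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("mpi,lab_code,alert_dt,stage,scr_at_alert", lines), path)
  path
}

# a tiny well-formed submission: 3 results, 1 alert
tiny_submission <- function() {
  scr <- write_scr_csv(c(
    "P1,L01,2019-01-01T09:00,80,1960-06-15,F,",
    "P1,L01,2019-02-01T09:00,82,1960-06-15,F,",
    "P2,L01,2019-01-15T10:30,95,1950-03-01,M,"))
  al <- write_alert_csv("P1,L01,2019-02-01T09:00,1,82")
  list(scr = scr, alerts = al)
}
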