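# Default adherence rubric: UI SFCH modification of Psychosocial Standards of
# Care Standard 1.A (youth assessments), levels 1-5 over two instruments.
# All windows are inclusive of both endpoints and computed at day resolution;
# month offsets use calendar-month arithmetic with day-of-month clamping.
name: uisfch-standard-1a
version: 1
swa:
  # "within 1 month of diagnosis" operationalized as [dx, dx + 30 days]
  initial_window_days: 30
pba:
  # "within 4 weeks of diagnosis" = [dx, dx + 28 days]; kept distinct from the
  # 30-day month convention because the rubric uses both phrasings
  initial_window_days: 28
  # "minimum of every 3 months throughout treatment": consecutive 3-calendar-
  # month bins from diagnosis; every complete bin needs >= 1 PBA, a trailing
  # partial bin imposes nothing
  treatment_bin_months: 3
  # "end of treatment (+/- 2 months of treatment completion)"
  eot_window_months: 2
  # "at least twice within the year following treatment completion (+/- 3
  # months)": >= min_events PBAs in (eot, eot + window_months]
  post_eot_year_window_months: 15
  post_eot_year_min_events: 2
annual:
  # "annually (12 +/- 3 months) following the end of treatment": window k is
  # [eot + 12k - 3 months, eot + 12k + 3 months], enumerated while the window
  # end is on or before the censor date
  anniversary_months: 12
  tolerance_months: 3
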