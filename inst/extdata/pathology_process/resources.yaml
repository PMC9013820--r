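calendars:
  weekday:
    windows:
    - 07:00-15:00
    days_per_week: 5.0
    weeks_per_year: 50.0
resources:
- name: cutting_technician
  fte: 1.0
  servers: 1
  calendar: weekday
  annual_hours_per_fte: 1776.0
- name: histology_technician
  fte: 2.0
  servers: 2
  calendar: weekday
  annual_hours_per_fte: 1776.0
- name: pathologist
  fte: 1.0
  servers: 1
  calendar: weekday
  annual_hours_per_fte: 1776.0
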