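2e06f12f2ac3c5eb26f5e0c9d5b3273f  trace_day.csv
ec52ca98cb98a45b695fb58a614f5709  exposure_day.csv
3c0b836a3537d11cb5398272251b34ea  routes_day.csv
06b8245d9ae3efb89e3e5b2518e3325c  pollutant_units.csv
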