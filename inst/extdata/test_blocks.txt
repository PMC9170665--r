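trialType fixedStopTime
go NaN
stop 200
go NaN
go NaN
go NaN
stop 300
go NaN
go NaN
go NaN
stop 400
go NaN
go NaN
go NaN
stop 500
go NaN
go NaN
go NaN
stop 600
go NaN
go NaN
go NaN
stop 200
go NaN
go NaN
go NaN
stop 300
go NaN
go NaN
go NaN
go NaN
stop 400
go NaN
go NaN
go NaN
stop 500
go NaN
go NaN
go NaN
stop 600
go NaN
go NaN
go NaN
stop 200
go NaN
go NaN
go NaN
stop 300
go NaN
go NaN
go NaN
stop 400
go NaN
go NaN
go NaN
stop 500
go NaN
go NaN
go NaN
stop 600
go NaN
go NaN
go NaN
stop 200
go NaN
go NaN
go NaN
stop 300
go NaN
go NaN
go NaN
stop 400
go NaN
go NaN
go NaN
stop 500
go NaN
go NaN
go NaN
go NaN
stop 600
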