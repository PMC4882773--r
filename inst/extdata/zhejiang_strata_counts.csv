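stratifier,stratum,gender,cases,n
age,45-59,male,48,235
age,60-74,male,94,273
age,75+,male,44,100
age,45-59,female,78,307
age,60-74,female,114,253
age,75+,female,41,96
smoking,never,male,60,179
smoking,current,male,126,428
smoking,never,female,227,642
smoking,current,female,6,14
alcohol,never,male,59,201
alcohol,current,male,38,93
alcohol,never,female,182,520
alcohol,current,female,23,55
bmi,<18.5,male,6,30
bmi,18.5-23.9,male,64,248
bmi,24.0-27.9,male,47,119
bmi,>=28.0,male,13,29
bmi,<18.5,female,9,31
bmi,18.5-23.9,female,60,242
bmi,24.0-27.9,female,77,158
bmi,>=28.0,female,30,55
whtr,pear,male,29,156
whtr,apple,male,103,272
whtr,pear,female,15,85
whtr,apple,female,163,408
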