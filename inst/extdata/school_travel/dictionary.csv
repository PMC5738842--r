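study_id,variable_id,name,label,description,unit,format,categories,variable_group,wave,respondent
SPEEDY,1,W1_school_travel,Mode of travel to school,How do you usually travel to school?,,categorical,Car;Bus/train;Bicycle;On foot,School_travel,1,child
SPEEDY,2,W1_a2actmins_clean,Duration walking to school,"Duration of journey when walking to school, minutes per day",minutes,continuous,,School_travel,1,child
SPEEDY,3,W1_a3actmins_clean,Duration cycling to school,"Duration of journey when cycling to school, minutes per day",minutes,continuous,,School_travel,1,child
SPEEDY,4,W1_travel_freq,Frequency of travel mode,How many times did you do this activity in the previous 7 days?,,categorical,Never;Once;2 to 3 times;4 or more times,School_travel,1,child
SPEEDY,5,sex,Sex,Participant sex,,categorical,Male;Female,Demographics,,child
SPEEDY,6,age,Age,Age at wave 1,years,continuous,,Demographics,,child
KISS,1,a_schulweg_hin_sommer,Mode of travel to school (summer),How does your child usually travel to school? Translated from German; summer item; journey to school.,,categorical,Walk;Cycle/scooter;Car;Bus/train/tram,School_travel,1,parent
KISS,2,a_schulweg_hin_sommer_time,Duration of journey to school,"Estimated journey duration in minutes, free text",minutes,continuous,,School_travel,1,parent
KISS,3,sex,Sex,Participant sex,,categorical,Male;Female,Demographics,,parent
KISS,4,age,Age,Age at wave 1,years,continuous,,Demographics,,parent
Ballabeina,1,W1_a_schulweg,Mode of travel to school,How does your child make it to school? Translated from French/German.,,categorical,Walk;Cycle/scooter;Bus/tram;Car;Other,School_travel,1,parent
Ballabeina,2,W1_a_langeweg,Duration of trip to school,What is the duration of the trip (one way) to get to school?,,categorical,<10 min;10–20 min;>20 min,School_travel,1,parent
Ballabeina,3,sex,Sex,Participant sex,,categorical,Male;Female,Demographics,,parent
Ballabeina,4,age,Age,Age at wave 1,years,continuous,,Demographics,,parent
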